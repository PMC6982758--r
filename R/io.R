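# Delimited-text persistence for datasets and result tables, plus the JSON
# run manifest. All numbers are written with 17 significant digits so a
# written-and-reread dataset is lossless at double precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

write_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], fmt_num)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a multimodal dataset to a directory of delimited tables
#'
#' One wide delimited table per modality per subject (`ibi_<s>.tsv`,
#' `ecg_<s>.tsv`, `temperature_<s>.tsv`), shared `subjects.tsv`, `trials.tsv`
#' and `eeg_features.tsv` tables, and a JSON `manifest.json` recording the
#' design, effect model, seed and file inventory. [read_dataset()]
#' reconstructs the dataset losslessly.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param include_ecg write raw ECG traces too (default `TRUE` when present;
#'   these are by far the largest files).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, include_ecg = TRUE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(x, name) {
    write_tsv(x, file.path(dir, name))
    files <<- c(files, name)
  }
  put(dataset$subjects, "subjects.tsv")
  put(dataset$trials, "trials.tsv")
  if (!is.null(dataset$eeg_features)) put(dataset$eeg_features, "eeg_features.tsv")
  for (sc in names(dataset$ibi)) {
    tab <- do.call(rbind, lapply(seq_along(dataset$ibi[[sc]]), function(k) {
      ser <- dataset$ibi[[sc]][[k]]
      data.frame(trial = k, interval_ms = ser$intervals,
                 corrected = ser$corrected_mask)
    }))
    put(tab, sprintf("ibi_%s.tsv", sc))
  }
  if (include_ecg && !is.null(dataset$ecg)) {
    for (sc in names(dataset$ecg)) {
      tab <- do.call(rbind, lapply(seq_along(dataset$ecg[[sc]]), function(k) {
        tr <- dataset$ecg[[sc]][[k]]
        data.frame(trial = k, mv = tr$samples, fs = tr$fs)
      }))
      put(tab, sprintf("ecg_%s.tsv", sc))
    }
  }
  for (sc in names(dataset$temperature)) {
    tr <- dataset$temperature[[sc]]
    put(data.frame(time_s = tr$time_s, celsius = tr$celsius),
        sprintf("temperature_%s.tsv", sc))
  }
  manifest <- list(design = unclass(dataset$design),
                   effects = unclass(dataset$effects),
                   seed = dataset$effects$seed, files = files,
                   package_version = as.character(utils::packageVersion("valphys")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a multimodal dataset written by [write_dataset()]
#'
#' @param dir directory containing the tables and `manifest.json`.
#' @return a `multimodal_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop(sprintf("no manifest.json in '%s'", dir), call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  design <- do.call(study_design, man$design[setdiff(names(man$design), NULL)])
  eff_fields <- setdiff(names(man$effects), "eeg_heterogeneous")
  effects <- do.call(effect_model, c(man$effects[eff_fields],
    list(eeg_heterogeneous = isTRUE(man$effects$eeg_heterogeneous))))
  subjects <- read_tsv(file.path(dir, "subjects.tsv"))
  trials <- read_tsv(file.path(dir, "trials.tsv"))
  eegf <- if ("eeg_features.tsv" %in% man$files)
    read_tsv(file.path(dir, "eeg_features.tsv")) else NULL
  pick <- function(prefix) {
    fs <- grep(sprintf("^%s_.*\\.tsv$", prefix), man$files, value = TRUE)
    setNames(fs, sub(sprintf("^%s_(.*)\\.tsv$", prefix), "\\1", fs))
  }
  ibi <- lapply(pick("ibi"), function(f) {
    tab <- read_tsv(file.path(dir, f))
    lapply(split(tab, tab$trial), function(d)
      ibi_series(d$interval_ms, d$corrected))
  })
  ecg_files <- pick("ecg")
  ecg <- if (length(ecg_files) > 0) {
    lapply(ecg_files, function(f) {
      tab <- read_tsv(file.path(dir, f))
      lapply(split(tab, tab$trial), function(d) ecg_trace(d$mv, d$fs[1]))
    })
  } else NULL
  temperature <- lapply(pick("temperature"), function(f) {
    tab <- read_tsv(file.path(dir, f))
    list(time_s = tab$time_s, celsius = tab$celsius,
         fs = 1 / (tab$time_s[2] - tab$time_s[1]))
  })
  structure(list(design = design, effects = effects, subjects = subjects,
                 trials = trials, ibi = ibi, ecg = ecg,
                 temperature = temperature, eeg_features = eegf),
            class = "multimodal_dataset")
}
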