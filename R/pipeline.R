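# End-to-end orchestration: simulate (or read) -> per-modality features ->
# statistics -> feature selection -> fusion -> classification -> correlation,
# with every stage table written to disk and a JSON manifest that makes the
# run reproducible.

#' Full-run configuration
#'
#' @param design a [study_design()] (ignored when `input_dir` is given).
#' @param effects an [effect_model()].
#' @param input_dir optional directory of a written dataset to analyse
#'   instead of simulating.
#' @param out_dir output directory for stage tables and the manifest.
#' @param seed top-level seed; per-stage seeds are derived from it
#'   deterministically.
#' @param hrv_bands VLF/LF/HF ranges, see [frequency_domain_measures()].
#' @param sa_steps annealing steps per classifier (default 500).
#' @param classifiers classifiers to run (default both).
#' @param render_ecg simulate raw ECG traces and run the full detection
#'   pipeline (default `TRUE`); `FALSE` computes HRV from the inter-beat
#'   series directly.
#' @return list of class `run_config`.
#' @export
run_config <- function(design = study_design(), effects = effect_model(),
                       input_dir = NULL, out_dir = tempfile("valphys_run_"),
                       seed = 1,
                       hrv_bands = list(vlf = c(0.003, 0.04),
                                        lf = c(0.04, 0.15),
                                        hf = c(0.15, 0.40)),
                       sa_steps = 500, classifiers = c("knn", "qda"),
                       render_ecg = TRUE) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop_config("input_dir", sprintf("does not exist: '%s'", input_dir))
  structure(list(design = design, effects = effects, input_dir = input_dir,
                 out_dir = out_dir, seed = check_count(seed, "seed", 0L),
                 hrv_bands = hrv_bands, sa_steps = sa_steps,
                 classifiers = classifiers, render_ecg = render_ecg),
            class = "run_config")
}

#' Run the complete multimodal valence analysis
#'
#' Executes every stage on a simulated (or previously written) dataset:
#' HRV extraction (19 measures per trial), EEG band-power features and
#' asymmetry statistics, temperature segmentation/cleaning/statistics with
#' gender splits, HRV nonparametric statistics, simulated-annealing feature
#' selection, modality fusion, the modality x classifier x scheme
#' classification grid, gender-split SI classification and feature-rating
#' correlations. All stage tables are written to `config$out_dir` together
#' with a manifest (config, seeds, package version); re-running with the same
#' configuration reproduces every number.
#'
#' @param config a [run_config()].
#' @return invisible list (the report bundle) with all stage tables.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  effects <- config$effects
  effects$seed <- derive_seed(config$seed, 2)
  dataset <- stage("simulate", {
    if (is.null(config$input_dir))
      generate_dataset(config$design, effects, render_ecg = config$render_ecg)
    else read_dataset(config$input_dir)
  })
  genders <- dataset$subjects

  hrv_table <- stage("hrv", hrv_for_trials(dataset, bands = config$hrv_bands))
  write_tsv(hrv_table, file.path(out, "hrv.tsv"))

  eeg_table <- stage("eeg_features", extract_feature_vectors(dataset))
  write_tsv(eeg_table, file.path(out, "eeg_features.tsv"))

  asym <- stage("asymmetry", list(
    SI = asymmetry_analysis(eeg_table, mode = "SI"),
    SD = asymmetry_analysis(eeg_table, mode = "SD")))
  write_tsv(asym$SI$ai_tests, file.path(out, "asymmetry_si.tsv"))
  write_tsv(asym$SD$ai_tests, file.path(out, "asymmetry_sd.tsv"))
  write_tsv(asym$SI$power_tests, file.path(out, "asymmetry_power_si.tsv"))

  temp_segments <- stage("temperature_segment", {
    do.call(rbind, lapply(names(dataset$temperature), function(sc) {
      seg <- segment_temperature(dataset$temperature[[sc]],
                                 temperature_annotations(dataset, as.integer(sc)))
      seg <- clean_segments(seg)
      seg$subject <- as.integer(sc)
      seg
    }))
  })
  write_tsv(temp_segments, file.path(out, "temperature_segments.tsv"))
  temp_stats <- stage("temperature_stats", list(
    SI = temperature_statistics(temp_segments, "SI"),
    SD = temperature_statistics(temp_segments, "SD"),
    women = temperature_statistics(temp_segments, "SI", genders, "women"),
    men = temperature_statistics(temp_segments, "SI", genders, "men")))
  write_tsv(do.call(rbind, lapply(names(temp_stats), function(nm) {
    t <- temp_stats[[nm]]$tests; t$analysis <- nm; t
  })), file.path(out, "temperature_tests.tsv"))
  write_tsv(temp_stats$SI$group_stats, file.path(out, "temperature_groups.tsv"))

  hrv_stats <- stage("hrv_stats", {
    meas <- hrv_measure_names()
    cc <- hrv_table[complete.cases(hrv_table[, meas]), ]
    ks <- do.call(rbind, lapply(meas, function(m) {
      r <- ks_normality(cc[[m]]); r$feature <- m; r
    }))
    mw <- function(d) do.call(rbind, lapply(meas, function(m)
      mann_whitney(d[[m]][d$label == "positive"],
                   d[[m]][d$label == "negative"], label = m)))
    si <- mw(cc); si$analysis <- "SI"
    sd_t <- do.call(rbind, lapply(split(cc, cc$subject), function(d) {
      r <- mw(d); r$subject <- d$subject[1]; r
    }))
    women <- mw(cc[cc$gender == "F", ]); women$analysis <- "women"
    men <- mw(cc[cc$gender == "M", ]); men$analysis <- "men"
    list(ks = ks, si = si, sd = sd_t, women = women, men = men)
  })
  write_tsv(rbind(hrv_stats$si, hrv_stats$women, hrv_stats$men),
            file.path(out, "hrv_tests.tsv"))
  write_tsv(hrv_stats$sd, file.path(out, "hrv_tests_sd.tsv"))
  write_tsv(hrv_stats$ks, file.path(out, "hrv_normality.tsv"))

  selection <- stage("feature_selection", {
    meas <- hrv_measure_names()
    cc <- hrv_table[complete.cases(hrv_table[, meas]), ]
    lapply(setNames(config$classifiers, config$classifiers), function(clf)
      anneal_select(cc[, meas], cc$label,
                    sa_config(classifier = clf, steps = config$sa_steps,
                              seed = derive_seed(config$seed, 3)),
                    groups = cc$subject))
  })
  sel_tab <- do.call(rbind, lapply(names(selection), function(clf)
    data.frame(classifier = clf, best_score = selection[[clf]]$best_score,
               n_selected = length(selection[[clf]]$selected),
               selected = paste(selection[[clf]]$selected, collapse = ","))))
  write_tsv(sel_tab, file.path(out, "selection.tsv"))

  fused <- stage("fusion", fuse_modalities(eeg_table, hrv_table, temp_segments))
  write_tsv(fused, file.path(out, "fused_features.tsv"))

  grid <- stage("classification", compare_modalities(
    fused, classifiers = config$classifiers,
    seed = derive_seed(config$seed, 4)))
  write_tsv(grid$grid, file.path(out, "classification_grid.tsv"))

  gender_cls <- stage("gender_classification", {
    lapply(setNames(config$classifiers, config$classifiers), function(clf)
      gender_split_classification(fused, clf,
                                  seed = derive_seed(config$seed, 5)))
  })
  gc_tab <- do.call(rbind, lapply(names(gender_cls), function(clf)
    do.call(rbind, lapply(names(gender_cls[[clf]]), function(g)
      data.frame(classifier = clf, group = g,
                 mean_f1 = gender_cls[[clf]][[g]]$mean_f1,
                 sd_f1 = gender_cls[[clf]][[g]]$sd_f1)))))
  write_tsv(gc_tab, file.path(out, "gender_classification.tsv"))

  correlations <- stage("correlation", {
    feats <- c(eeg_primary_features(), "nn50", "mean_temp")
    list(SD = feature_valence_correlation(fused, feats, "SD"),
         SI = feature_valence_correlation(fused, feats, "SI"))
  })
  write_tsv(correlations$SD, file.path(out, "correlation_sd.tsv"))
  write_tsv(correlations$SI, file.path(out, "correlation_si.tsv"))

  manifest <- list(
    seed = config$seed,
    design = unclass(config$design), effects = unclass(config$effects),
    hrv_bands = config$hrv_bands, sa_steps = config$sa_steps,
    classifiers = config$classifiers, render_ecg = config$render_ecg,
    stage_seeds = list(simulate = derive_seed(config$seed, 2),
                       selection = derive_seed(config$seed, 3),
                       classification = derive_seed(config$seed, 4),
                       gender = derive_seed(config$seed, 5)),
    package_version = as.character(utils::packageVersion("valphys")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_lines <- c(
    sprintf("valphys full analysis (seed %d)", config$seed),
    sprintf("subjects: %d; trials/subject: %d", config$design$n_subjects,
            config$design$trials_per_subject),
    sprintf("HRV rows: %d (19 measures)", nrow(hrv_table)),
    sprintf("EEG feature rows: %d; asymmetry pairs: %d", nrow(eeg_table),
            nrow(asym$SI$ai_tests)),
    sprintf("temperature means (pos/neg/base): %.3f / %.3f / %.3f",
            temp_stats$SI$group_stats$mean[
              match(c("positive", "negative", "baseline"),
                    temp_stats$SI$group_stats$condition)][1],
            temp_stats$SI$group_stats$mean[
              match("negative", temp_stats$SI$group_stats$condition)],
            temp_stats$SI$group_stats$mean[
              match("baseline", temp_stats$SI$group_stats$condition)]),
    sprintf("fused features: %d columns x %d rows",
            length(c(eeg_primary_features(), "nn50", "mean_temp")),
            nrow(fused)),
    "classification grid:",
    utils::capture.output(print(grid$grid)))
  writeLines(summary_lines, file.path(out, "summary.txt"))

  invisible(list(dataset = dataset, hrv = hrv_table, eeg = eeg_table,
                 asymmetry = asym, temperature_segments = temp_segments,
                 temperature_stats = temp_stats, hrv_stats = hrv_stats,
                 selection = selection, fused = fused,
                 classification = grid, gender_classification = gender_cls,
                 correlations = correlations, manifest = manifest,
                 out_dir = out))
}
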