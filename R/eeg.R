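# EEG preprocessing, band-power features and hemispheric asymmetry analysis.

#' Default frequency bands for EEG band power
#'
#' Conventional boundaries consistent with a 45 Hz low-pass: Alpha 8-12 Hz,
#' Beta1 12-20 Hz, Beta2 20-30 Hz, Gamma 30-45 Hz. Fully overridable wherever
#' a `bands` argument is accepted.
#'
#' @return named list of `c(lo, hi)` Hz ranges.
#' @export
default_eeg_bands <- function() {
  list(alpha = c(8, 12), beta1 = c(12, 20), beta2 = c(20, 30),
       gamma = c(30, 45))
}

#' Default electrode-region map (10/10 system)
#'
#' Standard neighbourhoods for the scalp regions used by the feature set:
#' prefrontal (PF), frontal midline (Fm), central midline (Cm), central (C),
#' parietal (P), parieto-occipital midline (POm) and occipital (O), split by
#' hemisphere where applicable.
#'
#' @return named list mapping region name to electrode labels.
#' @export
default_region_map <- function() {
  list(PF_left = c("Fp1", "AF3", "AF7"), PF_right = c("Fp2", "AF4", "AF8"),
       Fm = c("Fz", "AFz"), Cm = c("Cz", "FCz"),
       C_left = c("C3", "C5"), C_right = c("C4", "C6"),
       P_left = c("P3", "P5"), P_right = c("P4", "P6"),
       POm = c("POz", "Pz"), O_left = c("O1", "PO3"),
       O_right = c("O2", "PO4"))
}

# The 20 model features (region.band) plus the 4 auxiliary homologous powers
# needed to complete the 9 asymmetry pairs.
eeg_primary_features <- function() {
  c(paste0("PF_left.", c("alpha", "beta1", "beta2", "gamma")),
    paste0("PF_right.", c("alpha", "beta1", "beta2", "gamma")),
    paste0("Fm.", c("beta1", "gamma")),
    paste0("Cm.", c("alpha", "beta1")),
    paste0("POm.", c("beta1", "beta2")),
    "C_left.gamma", "C_right.gamma",
    "P_right.gamma",
    paste0("O_right.", c("beta1", "beta2", "gamma")))
}

eeg_auxiliary_features <- function() {
  c("P_left.gamma", paste0("O_left.", c("beta1", "beta2", "gamma")))
}

# The 9 lateralized region-band pairs entering the asymmetry analysis
# (midline regions excluded by construction).
asymmetry_pairs <- function() {
  data.frame(
    pair = c("PF-alpha", "PF-beta1", "PF-beta2", "PF-gamma",
             "C-gamma", "P-gamma", "O-beta1", "O-beta2", "O-gamma"),
    left = c(paste0("PF_left.", c("alpha", "beta1", "beta2", "gamma")),
             "C_left.gamma", "P_left.gamma",
             paste0("O_left.", c("beta1", "beta2", "gamma"))),
    right = c(paste0("PF_right.", c("alpha", "beta1", "beta2", "gamma")),
              "C_right.gamma", "P_right.gamma",
              paste0("O_right.", c("beta1", "beta2", "gamma"))),
    stringsAsFactors = FALSE)
}

#' Band-pass filter and re-reference raw EEG
#'
#' Zero-phase 4th-order Butterworth band-pass (default 0.5-45 Hz) applied per
#' channel, followed by common average referencing (each sample's mean over
#' channels subtracted). A pluggable `artifact_hook` is accepted for
#' component-based artifact removal but the default performs none (synthetic
#' data is generated clean).
#'
#' @param eeg numeric matrix, samples x channels (column names = electrode
#'   labels).
#' @param fs sampling rate in Hz (> 90).
#' @param band `c(lo, hi)` pass band in Hz.
#' @param artifact_hook optional `function(eeg, fs)` applied after filtering,
#'   before re-referencing.
#' @return filtered, CAR-referenced matrix of the same dimensions.
#' @export
preprocess_eeg <- function(eeg, fs, band = c(0.5, 45), artifact_hook = NULL) {
  if (!is.matrix(eeg) || ncol(eeg) < 2)
    stop("preprocess_eeg requires a matrix with at least 2 channels",
         call. = FALSE)
  if (fs <= 90) stop("sampling rate must exceed 90 Hz", call. = FALSE)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  out <- apply(eeg, 2, function(ch) signal::filtfilt(bf, ch))
  if (!is.null(artifact_hook)) out <- artifact_hook(out, fs)
  out - rowMeans(out)
}

#' Spectral band power of an EEG window
#'
#' Welch power spectral estimate averaged over an electrode set and integrated
#' over a frequency band.
#'
#' @param eeg numeric matrix, samples x channels, column names = electrodes.
#' @param fs sampling rate in Hz.
#' @param band `c(lo, hi)` Hz.
#' @param electrodes electrode labels to average over (default: all columns).
#' @return non-negative scalar power.
#' @export
band_power <- function(eeg, fs, band, electrodes = NULL) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie within (0, fs/2)", call. = FALSE)
  if (is.null(dim(eeg))) eeg <- matrix(eeg, ncol = 1)
  if (!is.null(electrodes)) {
    missing <- setdiff(electrodes, colnames(eeg))
    if (length(missing) > 0)
      stop(sprintf("electrodes not present: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    eeg <- eeg[, electrodes, drop = FALSE]
  }
  if (nrow(eeg) < 2 * fs / band[1])
    warning("window shorter than 2 cycles of the band lower edge",
            call. = FALSE)
  mean(apply(eeg, 2, function(ch) {
    ps <- welch_psd(ch, fs, nperseg = min(length(ch), 2L * round(fs)))
    df <- ps$freq[2] - ps$freq[1]
    sum(ps$psd[ps$freq >= band[1] & ps$freq < band[2]]) * df
  }))
}

#' Assemble per-window band-power feature vectors
#'
#' When the dataset already carries band-power features (the synthetic
#' generator's output) they are validated and passed through. When raw EEG is
#' present, one feature vector is computed per analysis window from the
#' preprocessed multichannel signal: each feature is the band power of its
#' region's electrode set.
#'
#' @param dataset a [generate_dataset()] result or compatible object.
#' @param regions region map, see [default_region_map()].
#' @param bands frequency bands, see [default_eeg_bands()].
#' @param window_s,window_overlap analysis window length (s) and fractional
#'   overlap used for the raw-EEG path.
#' @return data frame with keys `subject`, `gender`, `trial`, `window`,
#'   `label`, `valence_rating` and 24 power columns (20 primary features plus
#'   4 auxiliary homologous powers).
#' @export
extract_feature_vectors <- function(dataset, regions = default_region_map(),
                                    bands = default_eeg_bands(),
                                    window_s = 4, window_overlap = 0.5) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  need <- c(eeg_primary_features(), eeg_auxiliary_features())
  need_regions <- unique(sub("\\..*$", "", need))
  missing_r <- setdiff(need_regions, names(regions))
  if (length(missing_r) > 0)
    stop(sprintf("region map missing region(s): %s",
                 paste(missing_r, collapse = ", ")), call. = FALSE)
  if (!is.null(dataset$eeg_features)) {
    tab <- dataset$eeg_features
    missing_c <- setdiff(need, names(tab))
    if (length(missing_c) > 0)
      stop(sprintf("feature table missing column(s): %s",
                   paste(missing_c, collapse = ", ")), call. = FALSE)
    if (any(as.matrix(tab[, need]) < 0))
      stop("band powers must be non-negative", call. = FALSE)
    return(tab)
  }
  if (is.null(dataset$eeg_raw))
    stop("dataset has neither precomputed EEG features nor raw EEG",
         call. = FALSE)
  rows <- list()
  for (s in dataset$subjects$subject) {
    sc <- as.character(s)
    gender <- dataset$subjects$gender[dataset$subjects$subject == s]
    tr <- dataset$trials[dataset$trials$subject == s, ]
    for (k in seq_len(nrow(tr))) {
      raw <- dataset$eeg_raw[[sc]][[tr$trial[k]]]
      prep <- preprocess_eeg(raw$samples, raw$fs)
      colnames(prep) <- colnames(raw$samples)
      wlen <- round(window_s * raw$fs)
      step <- max(1L, round(wlen * (1 - window_overlap)))
      starts <- seq(1L, nrow(prep) - wlen + 1L, by = step)
      for (w in seq_along(starts)) {
        win <- prep[starts[w]:(starts[w] + wlen - 1L), , drop = FALSE]
        pows <- vapply(need, function(f) {
          parts <- strsplit(f, ".", fixed = TRUE)[[1]]
          band_power(win, raw$fs, bands[[parts[2]]], regions[[parts[1]]])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject = s, gender = gender, trial = tr$trial[k],
                     window = w, label = tr$label[k],
                     valence_rating = tr$valence_rating[k]),
          as.data.frame(as.list(pows)))
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("subject", "gender", "trial", "window", "label",
                  "valence_rating", need)
  rownames(out) <- NULL
  out
}

#' Hemispheric asymmetry index
#'
#' `(right - left) / (right + left)` of the band spectral power over
#' homologous hemispheric regions; positive values indicate rightward
#' lateralization of power.
#'
#' @param right,left non-negative spectral powers (vectorised).
#' @return values in `[-1, 1]`; `NA` where `right + left == 0`.
#' @export
asymmetry_index <- function(right, left) {
  den <- right + left
  ifelse(den > 0, (right - left) / den, NA_real_)
}

#' Asymmetry statistics over the 9 lateralized region-band pairs
#'
#' For each pair: (a) Mann-Whitney comparison of the per-observation asymmetry
#' index between positive and negative trials, and (b) Mann-Whitney comparison
#' of the raw left vs right powers within each condition. SI mode pools all
#' subjects' observations; SD mode tests within each subject.
#'
#' @param features an [extract_feature_vectors()] table (must include the
#'   auxiliary homologous powers).
#' @param mode `"SI"` or `"SD"`.
#' @return list with `ai_tests` (one row per pair, or per subject x pair in SD
#'   mode: U, p, median AI per condition, lateralization direction) and
#'   `power_tests` (left-vs-right tests within each condition).
#' @export
asymmetry_analysis <- function(features, mode = c("SI", "SD")) {
  mode <- match.arg(mode)
  pairs <- asymmetry_pairs()
  missing_c <- setdiff(c(pairs$left, pairs$right), names(features))
  if (length(missing_c) > 0)
    stop(sprintf("asymmetry analysis requires column(s): %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  if (!all(c("positive", "negative") %in% features$label))
    stop("both valence conditions must be present", call. = FALSE)
  analyse <- function(dat, subject = NA) {
    ai_rows <- list(); pw_rows <- list()
    for (k in seq_len(nrow(pairs))) {
      ai <- asymmetry_index(dat[[pairs$right[k]]], dat[[pairs$left[k]]])
      pos <- ai[dat$label == "positive"]
      neg <- ai[dat$label == "negative"]
      r <- mann_whitney(pos, neg, label = pairs$pair[k])
      ai_rows[[k]] <- data.frame(
        subject = subject, pair = pairs$pair[k], u = r$u, p = r$p,
        median_ai_positive = median(pos), median_ai_negative = median(neg),
        lateralization_positive = ifelse(median(pos) > 0, "right", "left"),
        lateralization_negative = ifelse(median(neg) > 0, "right", "left"))
      pw_rows[[k]] <- do.call(rbind, lapply(c("positive", "negative"),
        function(cond) {
          d <- dat[dat$label == cond, ]
          r2 <- mann_whitney(d[[pairs$left[k]]], d[[pairs$right[k]]],
                             label = pairs$pair[k])
          data.frame(subject = subject, pair = pairs$pair[k],
                     condition = cond, u = r2$u, p = r2$p,
                     direction = ifelse(r2$direction > 0, "left", "right"))
        }))
    }
    list(ai = do.call(rbind, ai_rows), pw = do.call(rbind, pw_rows))
  }
  if (mode == "SI") {
    res <- analyse(features)
  } else {
    parts <- lapply(split(features, features$subject),
                    function(d) analyse(d, d$subject[1]))
    res <- list(ai = do.call(rbind, lapply(parts, `[[`, "ai")),
                pw = do.call(rbind, lapply(parts, `[[`, "pw")))
  }
  rownames(res$ai) <- rownames(res$pw) <- NULL
  list(ai_tests = res$ai, power_tests = res$pw)
}
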