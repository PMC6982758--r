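# ECG preprocessing, inter-beat-interval extraction/correction and the 19
# heart-rate-variability measures (time domain, frequency domain, Poincare).

#' ECG trace container
#'
#' @param samples numeric vector, millivolts.
#' @param fs sampling rate in Hz.
#' @param annotations optional data frame of half-open sample windows
#'   (`start`, `end`, 1-based, `end` exclusive) marking trials.
#' @return object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, fs, annotations = NULL) {
  fs <- check_pos(fs, "fs")
  samples <- as.numeric(samples)
  if (!is.null(annotations)) {
    stopifnot(all(c("start", "end") %in% names(annotations)))
    if (any(annotations$start < 1 | annotations$end > length(samples) + 1))
      stop("annotations out of trace bounds", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, annotations = annotations),
            class = "ecg_trace")
}

#' Inter-beat-interval series
#'
#' @param intervals numeric vector of inter-beat intervals in milliseconds.
#' @param corrected_mask logical vector marking intervals replaced by
#'   interpolation (defaults to all `FALSE`).
#' @return object of class `ibi_series` with `intervals` (ms), cumulative
#'   `onset_times` (s) and `corrected_mask`.
#' @export
ibi_series <- function(intervals, corrected_mask = NULL) {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all inter-beat intervals must be positive", call. = FALSE)
  if (is.null(corrected_mask)) corrected_mask <- rep(FALSE, length(intervals))
  stopifnot(length(corrected_mask) == length(intervals))
  structure(list(intervals = intervals,
                 onset_times = cumsum(intervals) / 1000,
                 corrected_mask = as.logical(corrected_mask)),
            class = "ibi_series")
}

#' @export
length.ibi_series <- function(x) length(x$intervals)

#' High-pass filter an ECG trace
#'
#' Zero-phase 4th-order Butterworth high-pass (applied forward and backward),
#' the preprocessing step that suppresses baseline wander and T-wave content
#' so R peaks dominate the residual.
#'
#' @param trace an [ecg_trace()].
#' @param cutoff cut-off frequency in Hz (default 10).
#' @return filtered `ecg_trace`, same length and annotations.
#' @export
highpass_ecg <- function(trace, cutoff = 10) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (cutoff >= trace$fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(4, cutoff / (trace$fs / 2), type = "high")
  y <- signal::filtfilt(bf, trace$samples)
  ecg_trace(y, trace$fs, trace$annotations)
}

#' Detect R peaks in a filtered ECG trace
#'
#' Energy-based detector: the filtered signal is squared and integrated over a
#' moving 80 ms window; regions exceeding an adaptive threshold (rolling mean
#' plus 2 rolling standard deviations over 2 s) are scanned and the energy
#' centroid of each region taken as the beat location. A 200 ms refractory
#' rule suppresses the weaker of two candidates closer than that.
#'
#' @param trace a high-pass filtered [ecg_trace()] of at least 2 s.
#' @param refractory_s minimum beat spacing in seconds (default 0.2).
#' @return integer vector of strictly increasing sample indices (possibly
#'   empty, with a warning, when no peaks are found).
#' @export
detect_r_peaks <- function(trace, refractory_s = 0.2) {
  stopifnot(inherits(trace, "ecg_trace"))
  fs <- trace$fs
  x <- trace$samples
  if (length(x) < 2 * fs)
    stop("ECG trace must span at least 2 s for peak detection", call. = FALSE)
  sq <- x^2
  wi <- max(3L, round(0.08 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 2))
  mwi[is.na(mwi)] <- 0
  rs <- rolling_mean_sd(mwi, round(2 * fs))
  thr <- rs$mean + 2 * rs$sd
  above <- mwi > thr & mwi > 1e-12
  if (!any(above)) {
    warning("no R peaks found", call. = FALSE)
    return(integer(0))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  # merge regions separated by less than one QRS width (threshold fragmentation)
  if (length(starts) > 1) {
    gap_lim <- round(0.06 * fs)
    keep_r <- c(TRUE, starts[-1] - ends[-length(ends)] > gap_lim)
    grp <- cumsum(keep_r)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  peaks <- mapply(function(s, e) s - 1L + which.max(mwi[s:e]), starts, ends)
  # refine: energy centroid of the squared signal over a fixed-width window
  # centered on the candidate (the QRS energy is symmetric about the beat, so
  # the centroid localises the beat independently of threshold-crossing edges)
  half2 <- round(0.04 * fs)
  n <- length(sq)
  peaks <- vapply(peaks, function(p) {
    for (it in 1:3) {
      idx <- max(1L, p - half2):min(n, p + half2)
      cen <- sum(idx * sq[idx]) / sum(sq[idx])
      p2 <- as.integer(round(cen))
      if (p2 == p) break
      p <- p2
    }
    as.integer(round(cen))
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory: greedily keep the stronger of any pair closer than the limit
  min_gap <- round(refractory_s * fs)
  keep <- logical(length(peaks))
  last <- -Inf; last_i <- 0L
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= min_gap) {
      keep[i] <- TRUE; last <- peaks[i]; last_i <- i
    } else if (mwi[peaks[i]] > mwi[peaks[last_i]]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE
      last <- peaks[i]; last_i <- i
    }
  }
  peaks[keep]
}

#' Extract inter-beat intervals from detected peaks
#'
#' @param peaks strictly increasing sample indices of R peaks.
#' @param fs sampling rate in Hz.
#' @return an [ibi_series()] of `length(peaks) - 1` intervals in ms.
#' @export
peaks_to_ibi <- function(peaks, fs) {
  if (length(peaks) < 2)
    stop("at least two peaks are needed to form intervals", call. = FALSE)
  ibi_series(diff(peaks) / fs * 1000)
}

#' Detect and correct artifactual inter-beat intervals
#'
#' Intervals deviating more than `threshold` (default 25%) from the median of
#' the previous 5 clean intervals are flagged as artifacts (ectopic beats,
#' missed or false detections) and replaced by shape-preserving piecewise
#' cubic (PCHIP) interpolation over the neighbouring clean intervals, which
#' cannot overshoot beyond the neighbours. Trials with more than
#' `max_flagged` fraction flagged are rejected as unusable.
#'
#' @param series an [ibi_series()] with at least 4 intervals.
#' @param threshold relative deviation that flags an interval (default 0.25).
#' @param max_flagged maximum tolerated fraction of flagged intervals
#'   (default 0.2); beyond it an error of class `valphys_quality_error` is
#'   thrown.
#' @param method `"pchip"` (default, shape-preserving) or `"cubic"`
#'   (classical cubic spline).
#' @return corrected `ibi_series`; `corrected_mask` marks replacements.
#' @export
correct_ibi_artifacts <- function(series, threshold = 0.25, max_flagged = 0.2,
                                  method = c("pchip", "cubic")) {
  stopifnot(inherits(series, "ibi_series"))
  method <- match.arg(method)
  x <- series$intervals
  n <- length(x)
  if (n < 4)
    stop("artifact correction needs at least 4 intervals", call. = FALSE)
  flagged <- logical(n)
  clean_vals <- numeric(0)
  overall_med <- median(x)
  for (i in seq_len(n)) {
    ref <- if (length(clean_vals) == 0) overall_med else
      median(tail(clean_vals, 5))
    if (abs(x[i] - ref) > threshold * ref) {
      flagged[i] <- TRUE
    } else {
      clean_vals <- c(clean_vals, x[i])
    }
  }
  if (mean(flagged) > max_flagged) {
    cnd <- structure(class = c("valphys_quality_error", "error", "condition"),
                     list(message = sprintf(
                       "trial rejected: %.0f%% of intervals flagged as artifacts (limit %.0f%%)",
                       100 * mean(flagged), 100 * max_flagged), call = NULL))
    stop(cnd)
  }
  if (any(flagged)) {
    idx <- which(!flagged)
    if (length(idx) < 2)
      stop("too few clean intervals to interpolate", call. = FALSE)
    xi <- which(flagged)
    # clamp extrapolation at the edges to the nearest clean value
    xi_in <- pmin(pmax(xi, min(idx)), max(idx))
    y <- if (method == "pchip") pracma::pchip(idx, x[idx], xi_in)
         else spline(idx, x[idx], xout = xi_in, method = "fmm")$y
    x[xi] <- y
  }
  ibi_series(x, corrected_mask = flagged | series$corrected_mask)
}

#' Time-domain HRV measures
#'
#' Mean and median interval, SDNN (population standard deviation of the NN
#' intervals), RMSSD (root mean square of successive differences), NN50 (number
#' of adjacent pairs differing by more than 50 ms) and pNN50 = NN50 / (n - 1),
#' the proportion of such pairs.
#'
#' @param series an [ibi_series()] with at least 2 intervals.
#' @return one-row data frame: `mean_rr`, `median_rr`, `sdnn`, `rmssd`,
#'   `nn50`, `pnn50`.
#' @export
time_domain_measures <- function(series) {
  stopifnot(inherits(series, "ibi_series"))
  x <- series$intervals
  n <- length(x)
  if (n < 2)
    stop("time-domain measures need at least 2 intervals", call. = FALSE)
  d <- diff(x)
  nn50 <- sum(abs(d) > 50)
  data.frame(mean_rr = mean(x), median_rr = median(x),
             sdnn = sqrt(var_pop(x)), rmssd = sqrt(mean(d^2)),
             nn50 = nn50, pnn50 = nn50 / (n - 1))
}

#' Frequency-domain HRV measures
#'
#' Band powers of the inter-beat-interval tachogram integrated from a
#' Lomb-Scargle periodogram evaluated directly on the unevenly spaced beat
#' times (no resampling). Absolute power in ms^2, percentage of the total
#' power over the scanned range, normalised units for LF and HF
#' (`lf_nu = 100 LF / (LF + HF)`), and the LF/HF ratio.
#'
#' @param series an [ibi_series()].
#' @param bands named list of `c(lo, hi)` Hz ranges for `vlf`, `lf`, `hf`.
#'   Default VLF 0.003-0.04, LF 0.04-0.15, HF 0.15-0.4.
#' @param oversample frequency-grid oversampling factor (default 4).
#' @param method `"lomb"` (default) or `"welch"` (cubic-spline resampling of
#'   the tachogram to 4 Hz followed by a Welch estimate).
#' @return one-row data frame: `vlf_abs`, `lf_abs`, `hf_abs`, `vlf_pct`,
#'   `lf_pct`, `hf_pct`, `lf_nu`, `hf_nu`, `lf_hf_ratio`, plus attribute
#'   `low_confidence` when the series spans less than 30 s.
#' @export
frequency_domain_measures <- function(series,
                                      bands = list(vlf = c(0.003, 0.04),
                                                   lf = c(0.04, 0.15),
                                                   hf = c(0.15, 0.40)),
                                      oversample = 4,
                                      method = c("lomb", "welch")) {
  stopifnot(inherits(series, "ibi_series"))
  method <- match.arg(method)
  b <- do.call(rbind, bands[c("vlf", "lf", "hf")])
  if (any(diff(as.vector(t(b))) < 0))
    stop("bands must be non-overlapping and increasing", call. = FALSE)
  t <- series$onset_times
  x <- series$intervals
  span <- diff(range(t))
  low_conf <- span < 30
  if (low_conf)
    warning("IBI series spans less than 30 s; frequency-domain measures are low-confidence",
            call. = FALSE)
  f_lo <- max(b[1, 1], 1 / span)
  f_hi <- b[3, 2]
  if (method == "lomb") {
    df <- 1 / (span * oversample)
    freq <- seq(f_lo, f_hi, by = df)
    pg <- lomb_periodogram(t, x, freq)
    pw <- pg$power
    # scale so that total integrated power over the scanned range equals the
    # sample variance of the tachogram (ms^2)
    tot_raw <- sum(pw) * df
    scale <- if (tot_raw > 0) var_pop(x) / tot_raw else 0
    band_power_of <- function(lo, hi) sum(pw[freq >= lo & freq < hi]) * df * scale
  } else {
    fs_r <- 4
    tr <- seq(min(t), max(t), by = 1 / fs_r)
    xr <- spline(t, x, xout = tr, method = "fmm")$y
    ps <- welch_psd(xr, fs_r, nperseg = min(length(xr), 256L))
    df <- ps$freq[2] - ps$freq[1]
    band_power_of <- function(lo, hi) sum(ps$psd[ps$freq >= lo & ps$freq < hi]) * df
  }
  vlf <- band_power_of(b[1, 1], b[1, 2])
  lf <- band_power_of(b[2, 1], b[2, 2])
  hf <- band_power_of(b[3, 1], b[3, 2])
  tot <- vlf + lf + hf
  pct <- if (tot > 0) c(vlf, lf, hf) / tot * 100 else rep(NA_real_, 3)
  nu_den <- lf + hf
  out <- data.frame(total_power = tot,
                    vlf_abs = vlf, lf_abs = lf, hf_abs = hf,
                    vlf_pct = pct[1], lf_pct = pct[2], hf_pct = pct[3],
                    lf_nu = if (nu_den > 0) 100 * lf / nu_den else NA_real_,
                    hf_nu = if (nu_den > 0) 100 * hf / nu_den else NA_real_,
                    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
  attr(out, "low_confidence") <- low_conf
  out
}

#' Poincare-plot HRV measures
#'
#' SD1 (dispersion perpendicular to the identity line of the lag-1 Poincare
#' plot; short-term variability) and SD2 (dispersion along it; long-term
#' variability), using population variances so that
#' `SD1^2 + SD2^2 = 2 SDNN^2` holds exactly.
#'
#' @param series an [ibi_series()] with at least 3 intervals.
#' @return one-row data frame: `sd1`, `sd2`, `sd1_sd2_ratio` (`NA` when
#'   SD2 = 0).
#' @export
poincare_measures <- function(series) {
  stopifnot(inherits(series, "ibi_series"))
  x <- series$intervals
  if (length(x) < 3)
    stop("Poincare measures need at least 3 intervals", call. = FALSE)
  vd <- var_pop(diff(x))
  v <- var_pop(x)
  sd1 <- sqrt(0.5 * vd)
  sd2 <- sqrt(max(2 * v - 0.5 * vd, 0))
  data.frame(sd1 = sd1, sd2 = sd2,
             sd1_sd2_ratio = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' All 19 HRV measures for one IBI series
#'
#' @inheritParams frequency_domain_measures
#' @return one-row data frame with the 6 time-domain, 9 frequency-domain and
#'   3 Poincare columns plus `n_beats`.
#' @export
hrv_measures <- function(series, bands = list(vlf = c(0.003, 0.04),
                                              lf = c(0.04, 0.15),
                                              hf = c(0.15, 0.40)),
                         method = "lomb") {
  cbind(time_domain_measures(series),
        suppressWarnings(frequency_domain_measures(series, bands,
                                                   method = method)),
        poincare_measures(series),
        n_beats = length(series) + 1L)
}

#' Names of the 19 HRV measures
#'
#' @param with_extras also include the bookkeeping column `n_beats`.
#' @return character vector of measure column names.
#' @export
hrv_measure_names <- function(with_extras = FALSE) {
  m <- c("mean_rr", "median_rr", "sdnn", "rmssd", "nn50", "pnn50",
         "total_power", "vlf_abs", "lf_abs", "hf_abs",
         "vlf_pct", "lf_pct", "hf_pct", "lf_nu", "hf_nu", "lf_hf_ratio",
         "sd1", "sd2", "sd1_sd2_ratio")
  if (with_extras) c(m, "n_beats") else m
}

#' HRV measures for every trial of selected subjects
#'
#' Runs the full per-trial pipeline — high-pass filter, R-peak detection, IBI
#' extraction, artifact correction, 19 measures — on the ECG of each trial.
#' When the dataset carries inter-beat intervals instead of raw ECG (the
#' generator's fast path) the detection steps are skipped and correction plus
#' the measures are computed directly.
#'
#' @param dataset a [generate_dataset()] result (or an object with the same
#'   structure read from disk).
#' @param subjects subject ids to process (default: all).
#' @param bands HRV frequency bands, see [frequency_domain_measures()].
#' @return data frame with keys `subject`, `gender`, `trial`, `label`,
#'   `valence_rating` and the 19 measure columns. Trials rejected by the
#'   artifact-quality rule yield rows of `NA` measures and a message.
#' @export
hrv_for_trials <- function(dataset, subjects = NULL,
                           bands = list(vlf = c(0.003, 0.04),
                                        lf = c(0.04, 0.15),
                                        hf = c(0.15, 0.40))) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (is.null(subjects)) subjects <- dataset$subjects$subject
  missing_ecg <- subjects[!vapply(as.character(subjects), function(s)
    !is.null(dataset$ecg[[s]]) || !is.null(dataset$ibi[[s]]), logical(1))]
  if (length(missing_ecg) > 0)
    stop(sprintf("ECG missing for subject(s): %s",
                 paste(missing_ecg, collapse = ", ")), call. = FALSE)
  rows <- list()
  for (s in subjects) {
    sc <- as.character(s)
    tr <- dataset$trials[dataset$trials$subject == s, ]
    gender <- dataset$subjects$gender[dataset$subjects$subject == s]
    for (k in seq_len(nrow(tr))) {
      ti <- tr$trial[k]
      series <- tryCatch({
        if (!is.null(dataset$ecg[[sc]])) {
          trace <- dataset$ecg[[sc]][[ti]]
          filt <- highpass_ecg(ecg_trace(trace$samples, trace$fs))
          peaks <- detect_r_peaks(filt)
          correct_ibi_artifacts(peaks_to_ibi(peaks, trace$fs))
        } else {
          correct_ibi_artifacts(dataset$ibi[[sc]][[ti]])
        }
      }, valphys_quality_error = function(e) {
        message(sprintf("subject %s trial %d: %s", sc, ti, conditionMessage(e)))
        NULL
      })
      meas <- if (is.null(series)) {
        nm <- hrv_measure_names(with_extras = TRUE)
        as.data.frame(setNames(as.list(rep(NA_real_, length(nm))), nm))
      } else hrv_measures(series, bands)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = s, gender = gender, trial = ti,
                   label = tr$label[k], valence_rating = tr$valence_rating[k]),
        meas)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
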