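# Wrist skin-temperature segmentation, outlier cleaning and statistics.

#' Segment a temperature trace into fixed-length trials
#'
#' Cuts one segment of `segment_s` seconds (half-open window, starting at
#' onset) out of the continuous trace for every annotated stimulus trial and
#' for every baseline period.
#'
#' @param trace list with `time_s` and `celsius` (regularly sampled; the
#'   sampling rate is inferred from the time step) or a data frame with those
#'   columns.
#' @param annotations data frame with `trial`, `onset_s`, `duration_s`,
#'   `condition` (`"positive"`, `"negative"` or `"baseline"`); baseline rows
#'   may use `trial = NA`.
#' @param segment_s segment length in seconds (default 28).
#' @param offset_s start of the segment relative to onset (default 0).
#' @return data frame of class `temp_segments`: one row per retained sample,
#'   columns `segment`, `trial`, `condition`, `time_s`, `celsius`, `cleaned`.
#' @export
segment_temperature <- function(trace, annotations, segment_s = 28,
                                offset_s = 0) {
  time_s <- trace$time_s
  celsius <- trace$celsius
  segs <- list()
  for (k in seq_len(nrow(annotations))) {
    a <- annotations[k, ]
    t0 <- a$onset_s + offset_s
    t1 <- t0 + segment_s
    if (t1 > max(time_s) + (time_s[2] - time_s[1]))
      stop(sprintf("trace too short for trial %s (needs %.0f s, have %.0f s)",
                   a$trial, t1, max(time_s)), call. = FALSE)
    i <- time_s >= t0 & time_s < t1
    segs[[k]] <- data.frame(segment = k,
                            trial = a$trial,
                            condition = a$condition,
                            time_s = time_s[i], celsius = celsius[i],
                            cleaned = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("temp_segments", "data.frame")
  out
}

#' Replace scaled-MAD outliers in a temperature segment
#'
#' Samples strictly more than `k` scaled median absolute deviations
#' (`1.4826 * MAD`, the consistency constant for a normal distribution) from
#' the segment median are treated as sensor artifacts and replaced by the mean
#' of the non-outlier samples. The strict inequality makes the `MAD = 0` case
#' behave sensibly: a constant segment flags nothing, while a segment that is
#' constant apart from isolated spikes flags exactly the spikes. The
#' flag-and-replace step is iterated to a fixed point (replacement tightens
#' the MAD, which can expose borderline samples), so the operation is
#' idempotent and never alters samples it did not flag.
#'
#' @param x numeric vector of temperature samples (at least 3).
#' @param k threshold in scaled-MAD units (default 3).
#' @return numeric vector with outliers replaced; attribute `n_replaced`
#'   records how many samples changed.
#' @export
clean_outliers <- function(x, k = 3) {
  if (length(x) < 3)
    stop("outlier cleaning needs at least 3 samples", call. = FALSE)
  n_replaced <- 0L
  # iterate to a fixed point: replacement tightens the MAD slightly, so a
  # borderline sample can only become an outlier, never the reverse; the
  # cleaned segment is then invariant under re-cleaning
  for (iter in 1:100) {
    med <- median(x)
    smad <- mad(x, constant = 1.4826)
    out <- abs(x - med) > k * smad  # strict: constant segments flag nothing
    if (!any(out)) break
    if (all(out))
      stop("degenerate segment: every sample flagged as an outlier",
           call. = FALSE)
    x[out] <- mean(x[!out])
    n_replaced <- n_replaced + sum(out)
  }
  attr(x, "n_replaced") <- n_replaced
  x
}

#' Clean every segment of a segmented temperature table
#'
#' @param segments a [segment_temperature()] result.
#' @inheritParams clean_outliers
#' @return the table with outliers replaced per segment and `cleaned = TRUE`.
#' @export
clean_segments <- function(segments, k = 3) {
  for (s in unique(segments$segment)) {
    i <- segments$segment == s
    segments$celsius[i] <- as.numeric(clean_outliers(segments$celsius[i], k))
  }
  segments$cleaned <- TRUE
  segments
}

#' Nonparametric condition statistics for skin temperature
#'
#' Mann-Whitney comparisons of the cleaned temperature samples between
#' positive vs negative, positive vs baseline and negative vs baseline
#' conditions, together with group means and standard deviations. SI mode
#' pools the samples of all subjects; SD mode tests within each subject.
#'
#' @param segments data frame with `subject`, `condition`, `celsius` (cleaned
#'   segments of one or more subjects; bind [clean_segments()] outputs and add
#'   a `subject` column).
#' @param mode `"SI"` (pooled) or `"SD"` (per subject).
#' @param genders optional data frame `subject`, `gender` enabling
#'   `gender_filter`.
#' @param gender_filter `"all"`, `"women"` or `"men"`.
#' @return list with `tests` (data frame of Mann-Whitney results, one row per
#'   comparison, plus `subject` in SD mode) and `group_stats` (mean, sd, n per
#'   condition).
#' @export
temperature_statistics <- function(segments, mode = c("SI", "SD"),
                                   genders = NULL,
                                   gender_filter = c("all", "women", "men")) {
  mode <- match.arg(mode)
  gender_filter <- match.arg(gender_filter)
  if (gender_filter != "all") {
    if (is.null(genders))
      stop("gender filter requires a subject-gender table", call. = FALSE)
    want <- if (gender_filter == "women") "F" else "M"
    keep <- genders$subject[genders$gender == want]
    segments <- segments[segments$subject %in% keep, ]
  }
  comps <- list(c("positive", "negative"),
                c("positive", "baseline"),
                c("negative", "baseline"))
  run_tests <- function(d, subject = NA) {
    do.call(rbind, lapply(comps, function(cc) {
      a <- d$celsius[d$condition == cc[1]]
      b <- d$celsius[d$condition == cc[2]]
      if (length(a) == 0 || length(b) == 0)
        stop(sprintf("empty condition group '%s'",
                     cc[which(c(length(a), length(b)) == 0)[1]]), call. = FALSE)
      r <- mann_whitney(a, b, label = paste(cc, collapse = "_vs_"))
      r$subject <- subject
      r
    }))
  }
  tests <- if (mode == "SI") run_tests(segments) else {
    do.call(rbind, lapply(split(segments, segments$subject),
                          function(d) run_tests(d, d$subject[1])))
  }
  rownames(tests) <- NULL
  gs <- do.call(rbind, lapply(split(segments, segments$condition), function(d)
    data.frame(condition = d$condition[1], mean = mean(d$celsius),
               sd = sd(d$celsius), n = nrow(d))))
  rownames(gs) <- NULL
  list(tests = tests, group_stats = gs)
}
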