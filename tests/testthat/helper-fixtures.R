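# Shared fixtures, built in code. Expensive datasets are generated once per
# test run and cached.

tiny_design <- function(n_subjects = 4, n_men = 2, trials = 6) {
  study_design(n_subjects = n_subjects, n_men = n_men,
               trials_per_subject = trials, trial_duration_s = c(30, 40))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_dataset <- function() {
  cached("default", generate_dataset(study_design(), effect_model(seed = 101),
                                     render_ecg = FALSE))
}

homogeneous_dataset <- function() {
  cached("homog", generate_dataset(
    study_design(),
    effect_model(seed = 102, eeg_heterogeneous = FALSE),
    render_ecg = FALSE))
}

randomsign_dataset <- function() {
  cached("rsign", generate_dataset(
    study_design(),
    effect_model(seed = 103, nn50_male_shift = 0, sd2_female_shift = 0,
                 temp_neg_shift = 0, eeg_asym_shift = 0,
                 eeg_subject_shift = 1.2, eeg_heterogeneous = TRUE),
    render_ecg = FALSE))
}

# cleaned per-subject temperature segments of a dataset, with subject column
dataset_segments <- function(ds) {
  do.call(rbind, lapply(names(ds$temperature), function(sc) {
    seg <- segment_temperature(ds$temperature[[sc]],
                               temperature_annotations(ds, as.integer(sc)))
    seg <- clean_segments(seg)
    seg$subject <- as.integer(sc)
    seg
  }))
}

fused_table <- function(key, ds) {
  cached(paste0("fused_", key), {
    suppressMessages(fuse_modalities(extract_feature_vectors(ds),
                                     hrv_for_trials(ds),
                                     dataset_segments(ds)))
  })
}

# Independent brute-force oracles for the time-domain and Poincare measures,
# written from the definitions (sample statistics, divide-by-n variances),
# deliberately avoiding the package's code paths.
oracle_time_poincare <- function(x) {
  n <- length(x)
  d <- x[-1] - x[-n]
  vp <- function(v) sum((v - sum(v) / length(v))^2) / length(v)
  nn50 <- sum(abs(d) > 50)
  c(mean_rr = sum(x) / n,
    median_rr = median(x),
    sdnn = sqrt(vp(x)),
    rmssd = sqrt(sum(d^2) / (n - 1)),
    nn50 = nn50,
    pnn50 = nn50 / (n - 1),
    sd1 = sqrt(0.5 * vp(d)),
    sd2 = sqrt(max(2 * vp(x) - 0.5 * vp(d), 0)))
}

# Exact two-sided Mann-Whitney p by full enumeration of all label
# arrangements (tie-free samples only).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(n, na), 2, u_of)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(p, 1)
}

make_planted_features <- function(n = 200, n_inform = 5, n_noise = 15,
                                  effect = 1.2, seed = 1) {
  set.seed(seed)
  y <- rep(c("positive", "negative"), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * (n_inform + n_noise)), nrow = n))
  names(x) <- c(paste0("inf", seq_len(n_inform)),
                paste0("noise", seq_len(n_noise)))
  for (k in seq_len(n_inform))
    x[[k]] <- x[[k]] + ifelse(y == "positive", effect / 2, -effect / 2)
  list(x = x, y = y)
}
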