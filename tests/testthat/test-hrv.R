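# Heart-rate-variability measures, ECG preprocessing and IBI correction.

test_that("time-domain measures match hand-computed examples", {
  td <- time_domain_measures(ibi_series(c(550, 610, 615, 700)))
  expect_equal(td$nn50, 2)            # successive diffs 60, 5, 85
  expect_equal(td$pnn50, 2 / 3)
  td2 <- time_domain_measures(ibi_series(c(500, 550, 540)))
  expect_equal(td2$rmssd, sqrt((50^2 + 10^2) / 2), tolerance = 1e-12)
  tdc <- time_domain_measures(ibi_series(rep(800, 10)))
  expect_equal(tdc$sdnn, 0)
  expect_equal(tdc$rmssd, 0)
  expect_equal(tdc$nn50, 0)
  expect_error(time_domain_measures(ibi_series(750)), "at least 2")
})

test_that("Poincare measures match hand computation and degenerate cases", {
  alt <- ibi_series(rep(c(800, 600), length.out = 7))  # 6 zero-mean diffs
  pc <- poincare_measures(alt)
  expect_equal(pc$sd1, sqrt(0.5) * 200, tolerance = 1e-12)
  pcc <- poincare_measures(ibi_series(rep(900, 5)))
  expect_equal(pcc$sd1, 0)
  expect_equal(pcc$sd2, 0)
  expect_true(is.na(pcc$sd1_sd2_ratio))
  expect_error(poincare_measures(ibi_series(c(800, 820))), "at least 3")
})

test_that("time-domain and Poincare measures equal the brute-force oracle", {
  set.seed(11)
  for (i in 1:200) {
    x <- runif(sample(5:120, 1), 400, 1500)
    ser <- ibi_series(x)
    got <- cbind(time_domain_measures(ser), poincare_measures(ser))
    want <- oracle_time_poincare(x)
    for (nm in names(want))
      expect_equal(got[[nm]], unname(want[nm]), tolerance = 1e-9)
    # Poincare identity, exact
    expect_equal(got$sd1^2 + got$sd2^2, 2 * got$sdnn^2, tolerance = 1e-9)
  }
})

test_that("artifact correction flags, interpolates and is idempotent", {
  clean <- ibi_series(seq(800, 830, length.out = 10))
  out <- correct_ibi_artifacts(clean)
  expect_equal(out$intervals, clean$intervals)
  expect_false(any(out$corrected_mask))

  ect <- ibi_series(c(800, 810, 400, 805, 795))
  fixed <- correct_ibi_artifacts(ect)
  expect_equal(which(fixed$corrected_mask), 3L)
  expect_gt(fixed$intervals[3], 795)
  expect_lt(fixed$intervals[3], 810)
  # shape-preserving cubic value, frozen from an independent PCHIP oracle
  expect_equal(fixed$intervals[3], 808.5714285714286, tolerance = 1e-9)
  again <- correct_ibi_artifacts(fixed)
  expect_equal(again$intervals, fixed$intervals)

  expect_error(correct_ibi_artifacts(ibi_series(c(800, 810, 790))),
               "at least 4")
  bad <- ibi_series(c(800, 810, 400, 1400, 420, 1500, 805, 795))
  expect_error(correct_ibi_artifacts(bad), class = "valphys_quality_error")
})

test_that("high-pass filter removes DC, keeps the passband, validates cutoff", {
  fs <- 256
  dc <- ecg_trace(rep(1, 4 * fs), fs)
  expect_lt(max(abs(highpass_ecg(dc)$samples[fs:(3 * fs)])), 1e-6)
  t <- seq(0, 4, by = 1 / fs)
  s20 <- ecg_trace(sin(2 * pi * 20 * t), fs)
  y <- highpass_ecg(s20)$samples
  mid <- y[(fs):(3 * fs)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)
  expect_error(highpass_ecg(dc, cutoff = 200), "Nyquist")
})

test_that("R-peak detection round-trips synthesized ECG within one sample", {
  fs <- 256
  for (s in 1:5) {
    set.seed(400 + s)
    rr <- runif(40, 600, 1100)
    pk <- detect_r_peaks(highpass_ecg(synthesize_ecg(rr, fs)))
    expect_length(pk, length(rr) + 1)
    expect_lte(max(abs(diff(pk) / fs * 1000 - rr)), 1000 / fs)
  }
  set.seed(1)
  pkc <- detect_r_peaks(highpass_ecg(synthesize_ecg(rep(1000, 15), fs)))
  expect_equal(unique(diff(pkc)), 256L)
})

test_that("detector handles flat traces, short traces and refractory beats", {
  fs <- 256
  expect_warning(pk <- detect_r_peaks(ecg_trace(rep(0, 4 * fs), fs)),
                 "no R peaks")
  expect_length(pk, 0)
  expect_error(detect_r_peaks(ecg_trace(rep(0, fs), fs)), "at least 2 s")
  # an ectopic-like deflection 150 ms after a true beat is suppressed
  set.seed(3)
  tr <- synthesize_ecg(c(800, 800, 800), fs)
  x <- tr$samples
  t <- (seq_along(x) - 1) / fs
  bt <- 0.5 + 0.8 + 0.15
  idx <- which(abs(t - bt) < 0.06)
  tt <- t[idx] - bt
  x[idx] <- x[idx] - (tt / 0.02) * exp(-tt^2 / (2 * 0.02^2)) * exp(0.5) * 0.7
  pk <- detect_r_peaks(highpass_ecg(ecg_trace(x, fs)))
  expect_length(pk, 4)
})

test_that("frequency-domain measures localise power and normalise correctly", {
  n <- 80
  hf <- ibi_series(850 + 50 * sin(2 * pi * 0.25 * (1:n) * 0.85))
  fd <- frequency_domain_measures(hf)
  expect_gte(fd$hf_pct, 95)
  expect_equal(fd$lf_nu + fd$hf_nu, 100, tolerance = 1e-9)
  both <- ibi_series(850 + 30 * sin(2 * pi * 0.10 * (1:n) * 0.85)
                         + 30 * sin(2 * pi * 0.25 * (1:n) * 0.85))
  fd2 <- frequency_domain_measures(both)
  expect_equal(fd2$lf_hf_ratio, 1, tolerance = 0.1)
  expect_equal(fd2$lf_nu + fd2$hf_nu, 100, tolerance = 1e-9)
  # random series: normalisation identity and percent bound
  set.seed(5)
  for (i in 1:10) {
    ser <- synthesize_ibi(60, 850)
    f <- frequency_domain_measures(ser)
    expect_equal(f$lf_nu + f$hf_nu, 100, tolerance = 1e-9)
    expect_lte(f$vlf_pct + f$lf_pct + f$hf_pct, 100 + 1e-9)
  }
  expect_warning(frequency_domain_measures(ibi_series(rep(800, 10))),
                 "low-confidence")
})

test_that("hrv_for_trials yields one full row per trial and flags missing ECG", {
  ds <- cached("tiny_ecg",
               generate_dataset(tiny_design(), effect_model(seed = 5),
                                render_ecg = TRUE))
  tab <- hrv_for_trials(ds, subjects = 1:2)
  expect_equal(nrow(tab), 2 * 6)
  expect_true(all(hrv_measure_names() %in% names(tab)))
  expect_length(hrv_measure_names(), 19)
  expect_true(all(complete.cases(tab[, hrv_measure_names()])))
  ds_miss <- generate_dataset(tiny_design(), effect_model(seed = 5),
                              render_ecg = FALSE, missing = list(ecg = 2))
  expect_error(hrv_for_trials(ds_miss), "subject\\(s\\): 2")
})
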