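# The synthetic multimodal generator: determinism, validation, planted
# effects and persistence.

test_that("invalid designs and effects are rejected naming the field", {
  expect_error(study_design(n_subjects = 0), "n_subjects")
  expect_error(study_design(n_men = 30), "n_men")
  expect_error(study_design(trials_per_subject = 7), "trials_per_subject")
  expect_error(study_design(trial_duration_s = c(78, 43)), "trial_duration_s")
  expect_error(effect_model(nn50_male_shift = -1), "nn50_male_shift")
  expect_error(effect_model(subject_heterogeneity = -0.1),
               "subject_heterogeneity")
})

test_that("identical seed and parameters give a bit-identical dataset", {
  a <- generate_dataset(tiny_design(), effect_model(seed = 7))
  b <- generate_dataset(tiny_design(), effect_model(seed = 7))
  expect_identical(a, b)
  c <- generate_dataset(tiny_design(), effect_model(seed = 8))
  expect_false(identical(a$trials$valence_rating, c$trials$valence_rating))
})

test_that("ratings and trial structure match the emulated study design", {
  ds <- default_dataset()
  expect_equal(nrow(ds$subjects), 24)
  expect_equal(sum(ds$subjects$gender == "M"), 16)
  expect_equal(nrow(ds$trials), 24 * 14)
  lab <- table(ds$trials$subject, ds$trials$label)
  expect_true(all(lab == 7))
  expect_true(all(ds$trials$duration_s >= 43 & ds$trials$duration_s <= 78))
  pos <- ds$trials$valence_rating[ds$trials$label == "positive"]
  neg <- ds$trials$valence_rating[ds$trials$label == "negative"]
  expect_equal(mean(pos), 7.51, tolerance = 0.1)
  expect_equal(mean(neg), 2.91, tolerance = 0.1)
  expect_true(all(ds$trials$valence_rating >= 1 & ds$trials$valence_rating <= 9))
})

test_that("synthesize_ibi validates input and hits its base heart rate", {
  expect_error(synthesize_ibi(1, 850), "n >= 2")
  ser <- synthesize_ibi(500, 857, seed = 2)
  expect_equal(60000 / mean(ser$intervals), 70, tolerance = 2)
  expect_true(all(diff(ser$onset_times) > 0))
})

test_that("synthesize_ecg validates the physiological range", {
  expect_error(synthesize_ecg(numeric(0), 256), "non-empty")
  expect_error(synthesize_ecg(c(800, 200), 256), "physiological range")
  expect_error(synthesize_ecg(c(800, 2500), 256), "physiological range")
})

test_that("null generator leaves valence groups exchangeable", {
  # p-values of rank tests on null features are roughly uniform
  set.seed(41)
  ps <- replicate(60, {
    nn <- sapply(1:14, function(i)
      time_domain_measures(synthesize_ibi(60, 850))$nn50)
    mann_whitney(nn[1:7], nn[8:14])$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted NN50 and SD2 shifts are realized in expectation", {
  set.seed(42)
  n_rep <- 150
  nb <- replicate(n_rep, time_domain_measures(synthesize_ibi(70, 850))$nn50)
  ns <- replicate(n_rep,
    time_domain_measures(synthesize_ibi(70, 850, nn50_extra = 10))$nn50)
  d <- mean(ns) - mean(nb)
  se <- sqrt(var(ns) / n_rep + var(nb) / n_rep)
  expect_lt(abs(d - 10), 2 * se + 0.3)
  s0 <- replicate(n_rep, poincare_measures(synthesize_ibi(70, 850))$sd2)
  s2 <- replicate(n_rep,
    poincare_measures(synthesize_ibi(70, 850, sd2_extra = 20))$sd2)
  d2 <- mean(s2) - mean(s0)
  se2 <- sqrt(var(s2) / n_rep + var(s0) / n_rep)
  expect_lt(abs(d2 - 20), 2 * se2 + 1)
  # NN50 planting does not leak into long-term variability
  sleak <- replicate(n_rep,
    poincare_measures(synthesize_ibi(70, 850, nn50_extra = 10))$sd2)
  expect_lt(abs(mean(sleak) - mean(s0)), 2.5)
})

test_that("dataset persistence round-trips losslessly", {
  ds <- generate_dataset(tiny_design(2, 1, 4), effect_model(seed = 9))
  dir <- tempfile("ds_")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$trials, ds$trials, tolerance = 0)
  expect_equal(back$subjects, ds$subjects)
  expect_equal(back$eeg_features, ds$eeg_features, tolerance = 0)
  for (sc in names(ds$ibi)) for (k in seq_along(ds$ibi[[sc]])) {
    expect_equal(back$ibi[[sc]][[k]]$intervals, ds$ibi[[sc]][[k]]$intervals,
                 tolerance = 0)
  }
  expect_equal(back$ecg[["1"]][[1]]$samples, ds$ecg[["1"]][[1]]$samples,
               tolerance = 0)
  expect_equal(back$temperature[["2"]]$celsius, ds$temperature[["2"]]$celsius,
               tolerance = 0)
  expect_identical(back$effects, ds$effects)
  unlink(dir, recursive = TRUE)
})

test_that("deliberately missing modalities are honoured", {
  ds <- generate_dataset(tiny_design(), effect_model(seed = 10),
                         render_ecg = FALSE,
                         missing = list(temperature = 3, ecg = 4))
  expect_null(ds$temperature[["3"]])
  expect_null(ds$ibi[["4"]])
  expect_false(is.null(ds$temperature[["1"]]))
})
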