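# EEG preprocessing, band power and asymmetry analysis.

test_that("common average reference zeroes the channel mean", {
  set.seed(2)
  fs <- 128
  eeg <- matrix(rnorm(6 * fs * 4), ncol = 4)
  out <- preprocess_eeg(eeg, fs)
  expect_lt(max(abs(rowMeans(out))), 1e-9)
  same <- matrix(rep(sin(2 * pi * 10 * seq(0, 6, by = 1 / fs)), 3), ncol = 3)
  expect_lt(max(abs(preprocess_eeg(same, fs))), 1e-9)
  expect_error(preprocess_eeg(matrix(rnorm(100), ncol = 1), fs),
               "at least 2 channels")
})

test_that("band-pass attenuates out-of-band components by 20 dB or more", {
  fs <- 200
  t <- seq(0, 8, by = 1 / fs)
  x60 <- cbind(a = sin(2 * pi * 60 * t), b = -sin(2 * pi * 60 * t))
  y <- preprocess_eeg(x60, fs)
  mid <- (2 * fs):(6 * fs)
  expect_lt(max(abs(y[mid, 1])) / 1, 10^(-20 / 20))
})

test_that("band power concentrates on the stimulating frequency", {
  fs <- 128
  t <- seq(0, 8, by = 1 / fs)
  x <- matrix(sin(2 * pi * 10 * t), ncol = 1)
  colnames(x) <- "O1"
  p_alpha <- band_power(x, fs, c(8, 12))
  p_tot <- band_power(x, fs, c(0.5, 45))
  expect_gte(p_alpha / p_tot, 0.9)
  expect_equal(band_power(matrix(0, 1024, 1), fs, c(8, 12)), 0)
  expect_error(band_power(x, fs, c(50, 70)), "within")
  expect_error(band_power(x, fs, c(8, 12), electrodes = "O2"), "not present")
})

test_that("white-noise band power scales with bandwidth", {
  set.seed(4)
  fs <- 128
  ratios <- replicate(20, {
    x <- matrix(rnorm(fs * 16), ncol = 1)
    band_power(x, fs, c(20, 40)) / band_power(x, fs, c(10, 20))
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("asymmetry index satisfies its algebraic properties", {
  expect_equal(asymmetry_index(2, 1), 1 / 3)
  expect_equal(asymmetry_index(5, 5), 0)
  expect_equal(asymmetry_index(3, 0), 1)
  expect_true(is.na(asymmetry_index(0, 0)))
  grid <- expand.grid(r = c(0, 0.1, 1, 2, 7, 100), l = c(0, 0.1, 1, 2, 7, 100))
  grid <- grid[grid$r + grid$l > 0, ]
  ai <- asymmetry_index(grid$r, grid$l)
  expect_true(all(ai >= -1 & ai <= 1))
  expect_equal(ai, -asymmetry_index(grid$l, grid$r))
  for (k in c(0.5, 3, 17))
    expect_equal(asymmetry_index(k * grid$r, k * grid$l), ai)
})

test_that("feature tables expose 20 primary and 4 auxiliary band powers", {
  ds <- default_dataset()
  tab <- extract_feature_vectors(ds)
  prim <- valphys:::eeg_primary_features()
  aux <- valphys:::eeg_auxiliary_features()
  expect_length(prim, 20)
  expect_length(aux, 4)
  expect_true(all(c(prim, aux) %in% names(tab)))
  expect_true(all(as.matrix(tab[, c(prim, aux)]) >= 0))
  # midline regions never enter asymmetry pairs
  pairs <- valphys:::asymmetry_pairs()
  expect_equal(nrow(pairs), 9)
  expect_false(any(grepl("Fm|Cm|POm", c(pairs$left, pairs$right))))
  expect_error(extract_feature_vectors(ds, regions = list(PF_left = "Fp1")),
               "missing region")
})

test_that("raw-EEG path computes windowed band powers per region", {
  regions <- default_region_map()
  electrodes <- unique(unlist(regions))
  fs <- 128
  n <- 10 * fs
  set.seed(8)
  raw <- matrix(rnorm(n * length(electrodes), sd = 0.5), ncol = length(electrodes))
  colnames(raw) <- electrodes
  t <- (seq_len(n) - 1) / fs
  raw[, "Fp1"] <- raw[, "Fp1"] + 3 * sin(2 * pi * 10 * t)  # alpha at PF left
  ds <- structure(list(
    design = tiny_design(1, 1, 2),
    subjects = data.frame(subject = 1, gender = "M"),
    trials = data.frame(subject = 1, trial = 1:2, label = c("positive", "negative"),
                        valence_rating = c(7, 3), arousal_rating = c(4, 5),
                        onset_s = c(30, 80), duration_s = c(10, 10)),
    eeg_raw = list(`1` = list(list(samples = raw, fs = fs),
                              list(samples = raw, fs = fs))),
    eeg_features = NULL), class = "multimodal_dataset")
  tab <- extract_feature_vectors(ds)
  expect_equal(nrow(tab), 2 * 4)  # 10 s trials, 4 s windows, 50% overlap
  expect_true(mean(tab$PF_left.alpha) > mean(tab$PF_right.alpha))
})

test_that("asymmetry analysis recovers a planted prefrontal lateralization", {
  ds <- cached("asym", generate_dataset(
    study_design(),
    effect_model(seed = 104, eeg_asym_shift = 0.6, eeg_subject_shift = 0,
                 eeg_heterogeneous = FALSE),
    render_ecg = FALSE))
  res <- asymmetry_analysis(extract_feature_vectors(ds), mode = "SI")
  expect_equal(nrow(res$ai_tests), 9)
  pf <- res$ai_tests[res$ai_tests$pair == "PF-alpha", ]
  expect_lt(pf$p, 0.05)
  expect_equal(pf$lateralization_positive, "left")
  expect_equal(pf$lateralization_negative, "right")
  ob <- res$ai_tests[res$ai_tests$pair == "O-beta1", ]
  expect_equal(ob$lateralization_positive, "right")
  # SD mode: one row per subject and pair
  sd_res <- asymmetry_analysis(
    extract_feature_vectors(ds)[extract_feature_vectors(ds)$subject <= 3, ],
    mode = "SD")
  expect_equal(nrow(sd_res$ai_tests), 3 * 9)
  one <- extract_feature_vectors(ds)
  expect_error(asymmetry_analysis(one[one$label == "positive", ]),
               "both valence conditions")
})
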