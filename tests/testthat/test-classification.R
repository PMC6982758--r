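# Fusion, SD/SI classification, leakage probes and gender splits.

test_that("fusion joins the three modalities on subject and trial keys", {
  ds <- default_dataset()
  eeg <- extract_feature_vectors(ds)
  hrv <- hrv_for_trials(ds)
  seg <- dataset_segments(ds)
  fused <- fused_table("default", ds)
  feats <- c(valphys:::eeg_primary_features(), "nn50", "mean_temp")
  expect_length(feats, 22)
  expect_true(all(feats %in% names(fused)))
  expect_false(any(is.na(fused[, feats])))
  # key-stable: shuffled input row order gives the same content
  set.seed(51)
  fused2 <- suppressMessages(fuse_modalities(
    eeg[sample(nrow(eeg)), ], hrv[sample(nrow(hrv)), ], seg))
  expect_equal(fused2, fused)
  # a subject missing a modality disappears with a message
  expect_message(
    f3 <- fuse_modalities(eeg, hrv[hrv$subject != 5, ], seg),
    "missing a modality.*5")
  expect_false(5 %in% f3$subject)
  expect_error(fuse_modalities(eeg[eeg$subject == 1, ],
                               hrv[hrv$subject == 2, ],
                               seg[seg$subject == 3, ]),
               "no subjects shared")
})

test_that("the QDA implementation agrees with an independent reference", {
  set.seed(52)
  x <- matrix(rnorm(400), ncol = 4)
  y <- rep(c("a", "b"), each = 50)
  x[y == "b", ] <- x[y == "b", ] + 0.8
  fit <- valphys:::fit_qda(x, y)
  ref <- MASS::qda(x, factor(y))
  xt <- matrix(rnorm(200), ncol = 4)
  expect_equal(valphys:::predict_qda(fit, xt),
               as.character(predict(ref, xt)$class))
})

test_that("f1 score follows the standard positive-class definition", {
  truth <- c("positive", "positive", "negative", "negative")
  pred <- c("positive", "negative", "negative", "positive")
  sc <- f1_score(truth, pred)
  expect_equal(unname(sc["f1"]), 0.5)
  expect_equal(unname(f1_score(truth, truth)["f1"]), 1)
  expect_equal(unname(f1_score(truth, rep("negative", 4))["f1"]), 0)
})

test_that("separable homogeneous effects give near-perfect SD scores", {
  fused <- fused_table("homog", homogeneous_dataset())
  sd_knn <- classify(fused, "SD", "knn", seed = 2)
  expect_gte(sd_knn$mean_f1, 0.95)
  expect_true(all(sd_knn$per_unit$f1 >= 0 & sd_knn$per_unit$f1 <= 1))
  expect_equal(nrow(sd_knn$per_unit), 24)
  # determinism
  again <- classify(fused, "SD", "knn", seed = 2)
  expect_identical(again$per_unit, sd_knn$per_unit)
})

test_that("per-subject random-sign effects defeat SI transfer", {
  fused <- fused_table("rsign", randomsign_dataset())
  si <- classify(fused, "SI", "knn",
                 features = valphys:::eeg_primary_features())
  expect_lt(abs(si$mean_f1 - 0.5), 0.1)
})

test_that("shuffled labels collapse SD performance to chance", {
  fused <- fused_table("homog", homogeneous_dataset())
  sh <- fused
  set.seed(53)
  sh$label <- sample(sh$label)
  out <- classify(sh, "SD", "knn", seed = 3)
  expect_lt(abs(out$mean_f1 - 0.5), 0.1)
})

test_that("no training-fold leakage: label probe wins, fold probe does not", {
  fused <- fused_table("rsign", randomsign_dataset())
  probe <- fused[fused$subject <= 8, ]
  probe$cheat <- as.numeric(probe$label == "positive")
  out <- classify(probe, "SD", "knn", features = "cheat", seed = 4)
  expect_equal(out$mean_f1, 1)
  # a feature identifying the held-out unit carries no class information
  probe$unit_id <- probe$subject
  out2 <- classify(probe, "SI", "knn", features = "unit_id", seed = 4)
  expect_lt(abs(out2$mean_f1 - 0.5), 0.2)
})

test_that("the modality grid covers sets x classifiers x schemes plus chance", {
  fused <- fused_table("homog", homogeneous_dataset())
  small <- fused[fused$subject <= 6, ]
  res <- compare_modalities(small, modalities = c("eeg", "t_ecg"),
                            classifiers = "knn", schemes = "SD", seed = 5)
  expect_equal(nrow(res$grid), 2 + 1)
  expect_true("chance" %in% res$grid$modality)
  expect_error(classify(small, "SD", "knn", features = "not_there"),
               "missing")
  expect_error(valphys:::modality_features("bogus"), "unknown modality")
})

test_that("gender-split SI classification warns on small groups", {
  fused <- fused_table("homog", homogeneous_dataset())
  expect_warning(
    res <- gender_split_classification(fused, "knn", seed = 6),
    "< 15")
  expect_named(res, c("all", "women", "men"))
  expect_true(all(sapply(res, function(o) o$mean_f1 >= 0 && o$mean_f1 <= 1)))
  men_only <- fused[fused$gender == "M", ]
  expect_error(gender_split_classification(men_only, "knn"), "both genders")
})
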