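# Shared nonparametric statistics.

test_that("z-scoring standardises globally and within subject", {
  set.seed(31)
  tab <- data.frame(subject = rep(1:4, each = 25), a = rnorm(100, 5, 2),
                    b = runif(100))
  z <- zscore_features(tab, c("a", "b"))
  expect_equal(mean(z$a), 0, tolerance = 1e-9)
  expect_equal(sd(z$a), 1, tolerance = 1e-9)
  zps <- zscore_features(tab, c("a", "b"), grouping = "per-subject")
  for (s in 1:4) {
    expect_equal(mean(zps$a[zps$subject == s]), 0, tolerance = 1e-9)
    expect_equal(sd(zps$b[zps$subject == s]), 1, tolerance = 1e-9)
  }
  tab$c <- 3
  expect_error(zscore_features(tab, "c"), "zero-variance column 'c'")
})

test_that("KS normality check accepts normal and rejects exponential data", {
  set.seed(32)
  p_norm <- replicate(20, ks_normality(rnorm(1000))$p)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- replicate(20, ks_normality(rexp(1000))$p)
  expect_gte(mean(p_exp < 0.01), 0.95)
  expect_error(ks_normality(rnorm(3)), "at least 5")
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$u), 0)
  expect_equal(r$p, 0.1)     # 2/20 arrangements as extreme
  expect_equal(r$direction, -1)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  set.seed(33)
  for (i in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(seq_len(50), na + nb)  # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(mann_whitney(a, b)$p, oracle_mw_exact_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree at n = 8 per group", {
  set.seed(34)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    p_exact <- mann_whitney(a, b)$p
    p_approx <- mann_whitney(a, b, exact_max = 0)$p
    expect_lte(abs(p_exact - p_approx), 0.02)
  }
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(35)
  a <- rlnorm(12); b <- rlnorm(15, 0.4)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(log(a), log(b))$p)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(a^3, b^3)$p)
})

test_that("feature-rating correlation behaves in SD and SI modes", {
  set.seed(36)
  tab <- data.frame(subject = rep(1:3, each = 14),
                    valence_rating = runif(42, 1, 9))
  tab$mirror <- tab$valence_rating
  tab$noise <- rnorm(42)
  tab$flat <- 1
  si <- feature_valence_correlation(tab, c("mirror", "noise", "flat"), "SI")
  expect_equal(si$rho[si$feature == "mirror"], 1)
  expect_true(is.na(si$rho[si$feature == "flat"]))
  sd_res <- feature_valence_correlation(tab, c("mirror", "noise"), "SD")
  expect_equal(nrow(sd_res), 3 * 2)
  expect_true(all(sd_res$rho[sd_res$feature == "mirror"] == 1))
  # independent feature: mean coefficient near zero across replicates
  set.seed(37)
  rho <- replicate(200, {
    d <- data.frame(subject = 1, valence_rating = runif(14, 1, 9),
                    f = rnorm(14))
    feature_valence_correlation(d, "f", "SI")$rho
  })
  expect_lt(abs(mean(rho)), 0.06)
})

test_that("per-subject sign heterogeneity averages out in SI correlation", {
  ds <- randomsign_dataset()
  eeg <- extract_feature_vectors(ds)
  feats <- valphys:::eeg_primary_features()
  si <- feature_valence_correlation(eeg, feats, "SI")
  sd_res <- feature_valence_correlation(eeg, feats, "SD")
  # SD coefficients are strong and mixed-sign; SI coefficients are washed out
  strong <- abs(sd_res$rho) > 0.5
  expect_gt(mean(strong), 0.5)
  expect_true(any(sd_res$rho > 0.5) && any(sd_res$rho < -0.5))
  expect_lt(max(abs(si$rho)), 0.3)
})
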