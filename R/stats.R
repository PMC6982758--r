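# Shared nonparametric statistics used by every modality.

#' Z-score feature columns
#'
#' Standardises each feature column to mean 0 and standard deviation 1, either
#' globally or within subject (the grouping used before subject-dependent
#' statistics so that between-subject offsets do not masquerade as condition
#' effects).
#'
#' @param table data frame containing the feature columns.
#' @param columns character vector of column names to standardise; defaults to
#'   all numeric columns except `subject`, `trial` and `window`.
#' @param grouping `"global"` (one mean/sd per column) or `"per-subject"`
#'   (standardise within each level of `table$subject`).
#' @return `table` with the named columns standardised.
#' @export
zscore_features <- function(table, columns = NULL,
                            grouping = c("global", "per-subject")) {
  grouping <- match.arg(grouping)
  if (is.null(columns)) {
    num <- vapply(table, is.numeric, logical(1))
    columns <- setdiff(names(table)[num], c("subject", "trial", "window"))
  }
  zs <- function(x, col) {
    s <- sd(x)
    if (!is.finite(s) || s <= 0)
      stop(sprintf("zero-variance column '%s' cannot be z-scored", col),
           call. = FALSE)
    (x - mean(x)) / s
  }
  for (col in columns) {
    if (grouping == "global") {
      table[[col]] <- zs(table[[col]], col)
    } else {
      for (s in unique(table$subject)) {
        i <- table$subject == s
        table[[col]][i] <- zs(table[[col]][i], col)
      }
    }
  }
  table
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Standardises the sample and compares it with the standard normal
#' distribution. Because location and scale are estimated from the data the
#' test is conservative (Lilliefors situation); it is used here only as a
#' gate before switching to rank-based tests.
#'
#' @param sample numeric vector, `n >= 5`.
#' @return a one-row data frame (`test`, `statistic`, `p`, `n`).
#' @export
ks_normality <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 5) stop("ks_normality requires at least 5 observations", call. = FALSE)
  z <- (sample - mean(sample)) / sd(sample)
  res <- suppressWarnings(ks.test(z, "pnorm"))
  data.frame(test = "ks_normality", statistic = unname(res$statistic),
             p = res$p.value, n = n)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The exact null
#' distribution is used for small samples without ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_max use the exact distribution when both groups have at most
#'   this many observations and there are no ties (default 50).
#' @param label optional feature/test label carried into the result.
#' @return one-row data frame: `test`, `feature`, `u` (U statistic of `a`),
#'   `p`, `n_a`, `n_b`, `direction` (sign of median(a) - median(b)).
#' @export
mann_whitney <- function(a, b, exact_max = 50, label = NA_character_) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("mann_whitney requires two non-empty samples", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact))
  data.frame(test = "mann_whitney", feature = label,
             u = unname(res$statistic), p = min(res$p.value, 1),
             n_a = length(a), n_b = length(b),
             direction = sign(median(a) - median(b)))
}

#' Rank correlation of features with subjective valence ratings
#'
#' Correlates each feature column with the per-trial valence rating, either
#' per subject (SD mode: one coefficient per subject and feature) or pooled
#' over all subjects (SI mode). Spearman rank correlation by default,
#' consistent with the nonparametric treatment of the features themselves.
#'
#' @param table data frame with `subject`, a rating column and the feature
#'   columns.
#' @param features character vector of feature column names.
#' @param mode `"SD"` or `"SI"`.
#' @param rating_col name of the rating column (default `"valence_rating"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data frame with `subject` (`NA` for SI), `feature`, `rho`, `n`.
#'   Constant features yield `NA` coefficients.
#' @export
feature_valence_correlation <- function(table, features, mode = c("SD", "SI"),
                                        rating_col = "valence_rating",
                                        method = c("spearman", "pearson")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!rating_col %in% names(table))
    stop(sprintf("rating column '%s' missing", rating_col), call. = FALSE)
  if (any(!is.finite(table[[rating_col]])))
    stop("ratings must be present for all trials", call. = FALSE)
  corr_one <- function(dat) {
    r <- dat[[rating_col]]
    do.call(rbind, lapply(features, function(f) {
      x <- dat[[f]]
      rho <- if (sd(x) == 0 || sd(r) == 0) NA_real_ else
        suppressWarnings(cor(x, r, method = method))
      data.frame(feature = f, rho = rho, n = length(x))
    }))
  }
  if (mode == "SI") {
    out <- corr_one(table)
    out$subject <- NA_integer_
  } else {
    out <- do.call(rbind, lapply(split(table, table$subject), function(d) {
      r <- corr_one(d); r$subject <- d$subject[1]; r
    }))
    rownames(out) <- NULL
  }
  out[, c("subject", "feature", "rho", "n")]
}
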