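# Subject-dependent (SD) and subject-independent (SI) valence classification
# with KNN (k = 5) and QDA over configurable modality subsets.

# ---- classifiers ---------------------------------------------------------

# Gaussian quadratic discriminant classifier with optional shrinkage of each
# class covariance toward its diagonal; shrinkage 1e-3 is applied
# automatically (with a warning) when a class covariance is singular, which
# is routine in small training folds.
fit_qda <- function(x, y, shrinkage = 0) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("QDA needs two classes", call. = FALSE)
  fit_class <- function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    S <- crossprod(sweep(xi, 2, mu)) / max(nrow(xi) - 1, 1)
    if (shrinkage > 0)
      S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(S))
    ch <- try(chol(S), silent = TRUE)
    if (inherits(ch, "try-error")) {
      warning("singular class covariance; applying diagonal shrinkage 1e-3",
              call. = FALSE)
      S <- (1 - 1e-3) * S + 1e-3 * diag(diag(S) + 1e-8, ncol(S))
      ch <- chol(S)
    }
    list(mu = mu, chol = ch, prior = mean(y == cl),
         logdet = 2 * sum(log(diag(ch))))
  }
  structure(list(classes = classes,
                 fits = lapply(classes, fit_class)), class = "valphys_qda")
}

predict_qda <- function(model, x) {
  x <- as.matrix(x)
  scores <- vapply(model$fits, function(f) {
    z <- backsolve(f$chol, t(sweep(x, 2, f$mu)), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * f$logdet + log(f$prior)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
  model$classes[max.col(scores, ties.method = "first")]
}

predict_labels <- function(classifier, train_x, train_y, test_x) {
  if (classifier == "knn") {
    as.character(class::knn(as.matrix(train_x), as.matrix(test_x),
                            factor(train_y), k = 5))
  } else {
    as.character(predict_qda(fit_qda(train_x, train_y), test_x))
  }
}

#' Positive-class and macro F1 score
#'
#' Harmonic mean of precision and recall for the positive class; by the usual
#' convention a class with no predicted (or no true) members scores 0.
#'
#' @param truth,pred character vectors of labels.
#' @param positive the positive class label (default `"positive"`).
#' @return named numeric vector `c(f1, macro_f1)`.
#' @export
f1_score <- function(truth, pred, positive = "positive") {
  f1_one <- function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  classes <- unique(c(truth, pred))
  c(f1 = f1_one(positive), macro_f1 = mean(vapply(classes, f1_one, numeric(1))))
}

# ---- folds ---------------------------------------------------------------

# Stratified grouped k-fold: whole groups (trials) are dealt round-robin to
# folds within each label stratum, so windows of one trial never straddle a
# fold boundary.
grouped_stratified_folds <- function(groups, labels, k) {
  gl <- unique(data.frame(group = groups, label = labels))
  fold_of <- integer(nrow(gl))
  for (lb in unique(gl$label)) {
    i <- which(gl$label == lb)
    fold_of[i[sample(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  fold_of[match(groups, gl$group)]
}

# ---- modality feature sets ----------------------------------------------

modality_features <- function(set) {
  eeg <- eeg_primary_features()
  known <- list(eeg = eeg, t_ecg = c("mean_temp", "nn50"),
                eeg_t = c(eeg, "mean_temp"), eeg_ecg = c(eeg, "nn50"),
                eeg_t_ecg = c(eeg, "mean_temp", "nn50"))
  if (!set %in% names(known))
    stop(sprintf("unknown modality set '%s'", set), call. = FALSE)
  known[[set]]
}

# ---- fusion --------------------------------------------------------------

#' Fuse EEG, HRV and temperature features into trial feature vectors
#'
#' Key-joins the three per-modality tables on subject and trial: each EEG
#' window row of a trial receives that trial's NN50 count and mean cleaned
#' temperature (feature-level alignment in place of signal-level resampling).
#' Subjects missing any required modality are dropped with a message listing
#' them.
#'
#' @param eeg an [extract_feature_vectors()] table.
#' @param hrv an [hrv_for_trials()] table (supplies `nn50`).
#' @param temp cleaned segment table with `subject`, `trial`, `celsius`
#'   (stimulus segments; the per-trial mean becomes `mean_temp`).
#' @return data frame with keys (`subject`, `gender`, `trial`, `window`,
#'   `label`, `valence_rating`) and the 22 model features (20 EEG band powers
#'   + `nn50` + `mean_temp`), complete cases only.
#' @export
fuse_modalities <- function(eeg, hrv, temp) {
  temp_tr <- aggregate(celsius ~ subject + trial,
                       data = temp[!is.na(temp$trial), ], FUN = mean)
  names(temp_tr)[3] <- "mean_temp"
  common <- Reduce(intersect, list(unique(eeg$subject), unique(hrv$subject),
                                   unique(temp_tr$subject)))
  if (length(common) == 0)
    stop("no subjects shared across the three modality tables", call. = FALSE)
  dropped <- setdiff(unique(c(eeg$subject, hrv$subject, temp_tr$subject)),
                     common)
  if (length(dropped) > 0)
    message("subjects dropped from fusion (missing a modality): ",
            paste(sort(dropped), collapse = ", "))
  out <- eeg[eeg$subject %in% common, ]
  key <- function(d) paste(d$subject, d$trial)
  out$nn50 <- hrv$nn50[match(key(out), key(hrv))]
  out$mean_temp <- temp_tr$mean_temp[match(key(out), key(temp_tr))]
  feats <- c(eeg_primary_features(), "nn50", "mean_temp")
  out <- out[complete.cases(out[, feats]), ]
  out <- out[order(out$subject, out$trial, out$window), ]
  rownames(out) <- NULL
  out
}

# ---- core classification -------------------------------------------------

#' Valence classification in SD or SI mode
#'
#' SD: within each subject, stratified k-fold cross-validation over trials
#' (all windows of a trial stay in one fold); one F1 per subject, pooled over
#' that subject's held-out predictions. SI: leave-one-subject-out; one F1 per
#' held-out subject. Features are z-scored using training-fold statistics
#' only.
#'
#' @param table fused feature table ([fuse_modalities()] output or any table
#'   with `subject`, `trial`, `label` and the feature columns).
#' @param scheme `"SD"` or `"SI"`.
#' @param classifier `"knn"` (k = 5, Euclidean on z-scored features) or
#'   `"qda"`.
#' @param features feature column names (default: the 22 fused features
#'   present in the table).
#' @param genders optional `subject`/`gender` table for `gender_filter`.
#' @param gender_filter `"all"`, `"women"` or `"men"`.
#' @param k folds for SD mode (default 10, capped at the number of trials).
#' @param seed RNG seed controlling fold assignment.
#' @return list of class `classification_outcome`: `scheme`, `classifier`,
#'   `features`, `per_unit` (data frame: unit id, f1, macro_f1, n_test),
#'   `mean_f1`, `sd_f1`, `mean_macro_f1`, `seed`.
#' @export
classify <- function(table, scheme = c("SD", "SI"),
                     classifier = c("knn", "qda"), features = NULL,
                     genders = NULL, gender_filter = c("all", "women", "men"),
                     k = 10, seed = 1) {
  scheme <- match.arg(scheme)
  classifier <- match.arg(classifier)
  gender_filter <- match.arg(gender_filter)
  if (is.null(features)) {
    cand <- c(eeg_primary_features(), "nn50", "mean_temp")
    features <- intersect(cand, names(table))
  }
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0)
    stop(sprintf("feature column(s) missing: %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  if (gender_filter != "all") {
    gsrc <- genders %||% unique(table[, c("subject", "gender")])
    want <- if (gender_filter == "women") "F" else "M"
    keep <- gsrc$subject[gsrc$gender == want]
    if (length(keep) < 2)
      stop("gender group has fewer than 2 subjects", call. = FALSE)
    if (length(keep) < 15)
      warning(sprintf("%s group has only %d subjects (< 15); SI results are unstable",
                      gender_filter, length(keep)), call. = FALSE)
    table <- table[table$subject %in% keep, ]
  }
  zsc <- function(tr, te) {
    mu <- colMeans(tr); s <- apply(tr, 2, sd); s[!is.finite(s) | s <= 0] <- 1
    list(tr = sweep(sweep(tr, 2, mu), 2, s, `/`),
         te = sweep(sweep(te, 2, mu), 2, s, `/`))
  }
  run_unit <- function(dat, folds) {
    pred <- character(nrow(dat))
    for (f in sort(unique(folds))) {
      te <- folds == f
      if (length(unique(dat$label[!te])) < 2)
        stop("a training fold contains a single class", call. = FALSE)
      z <- zsc(as.matrix(dat[!te, features, drop = FALSE]),
               as.matrix(dat[te, features, drop = FALSE]))
      pred[te] <- predict_labels(classifier, z$tr, dat$label[!te], z$te)
    }
    f1_score(dat$label, pred)
  }
  per_unit <- if (scheme == "SD") {
    with_seed(derive_seed(seed, 11), {
      do.call(rbind, lapply(split(table, table$subject), function(d) {
        kk <- min(k, length(unique(d$trial)))
        folds <- grouped_stratified_folds(d$trial, d$label, kk)
        sc <- run_unit(d, folds)
        data.frame(unit = d$subject[1], f1 = sc[["f1"]],
                   macro_f1 = sc[["macro_f1"]], n_test = nrow(d))
      }))
    })
  } else {
    subs <- sort(unique(table$subject))
    if (length(subs) < 2)
      stop("SI classification needs at least 2 subjects", call. = FALSE)
    # seeded: the KNN backend breaks exact distance ties randomly
    with_seed(derive_seed(seed, 12), do.call(rbind, lapply(subs, function(s) {
      te <- table$subject == s
      z <- zsc(as.matrix(table[!te, features, drop = FALSE]),
               as.matrix(table[te, features, drop = FALSE]))
      pred <- predict_labels(classifier, z$tr, table$label[!te], z$te)
      sc <- f1_score(table$label[te], pred)
      data.frame(unit = s, f1 = sc[["f1"]], macro_f1 = sc[["macro_f1"]],
                 n_test = sum(te))
    })))
  }
  rownames(per_unit) <- NULL
  structure(list(scheme = scheme, classifier = classifier,
                 features = features, gender_filter = gender_filter,
                 per_unit = per_unit, mean_f1 = mean(per_unit$f1),
                 sd_f1 = sd(per_unit$f1),
                 mean_macro_f1 = mean(per_unit$macro_f1), seed = seed),
            class = "classification_outcome")
}

#' @export
print.classification_outcome <- function(x, ...) {
  cat(sprintf("%s / %s (%s): mean f1 = %.3f (s.d. %.3f) over %d units\n",
              x$scheme, toupper(x$classifier), x$gender_filter,
              x$mean_f1, x$sd_f1, nrow(x$per_unit)))
  invisible(x)
}

#' Classification outcomes across modality sets, classifiers and schemes
#'
#' Runs [classify()] for every combination of modality set (`eeg`, `t_ecg`,
#' `eeg_t`, `eeg_ecg`, `eeg_t_ecg`), classifier (`knn`, `qda`) and scheme
#' (`SD`, `SI`), keeping the per-unit F1 values for paired comparison, plus a
#' shuffled-label chance-level reference per scheme and classifier.
#'
#' @param table fused feature table.
#' @param modalities modality-set names (default all five).
#' @param classifiers,schemes subsets of `c("knn","qda")` / `c("SD","SI")`.
#' @param include_chance add shuffled-label reference rows (default `TRUE`).
#' @param seed RNG seed.
#' @return list: `grid` (data frame of mean/sd F1 per combination) and
#'   `outcomes` (named list of `classification_outcome` objects).
#' @export
compare_modalities <- function(table,
                               modalities = c("eeg", "t_ecg", "eeg_t",
                                              "eeg_ecg", "eeg_t_ecg"),
                               classifiers = c("knn", "qda"),
                               schemes = c("SD", "SI"),
                               include_chance = TRUE, seed = 1) {
  outcomes <- list(); rows <- list()
  for (m in modalities) {
    feats <- modality_features(m)
    for (clf in classifiers) for (sch in schemes) {
      o <- classify(table, scheme = sch, classifier = clf, features = feats,
                    seed = seed)
      key <- paste(m, clf, sch, sep = ".")
      outcomes[[key]] <- o
      rows[[key]] <- data.frame(modality = m, classifier = clf, scheme = sch,
                                mean_f1 = o$mean_f1, sd_f1 = o$sd_f1,
                                mean_macro_f1 = o$mean_macro_f1)
    }
  }
  if (include_chance) {
    shuffled <- table
    shuffled$label <- with_seed(derive_seed(seed, 99),
                                sample(table$label))
    for (clf in classifiers) for (sch in schemes) {
      o <- classify(shuffled, scheme = sch, classifier = clf,
                    features = modality_features("eeg_t_ecg"), seed = seed)
      key <- paste("chance", clf, sch, sep = ".")
      outcomes[[key]] <- o
      rows[[key]] <- data.frame(modality = "chance", classifier = clf,
                                scheme = sch, mean_f1 = o$mean_f1,
                                sd_f1 = o$sd_f1,
                                mean_macro_f1 = o$mean_macro_f1)
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  list(grid = grid, outcomes = outcomes)
}

#' Gender-split subject-independent classification
#'
#' SI classification with all 22 features for the whole population, women
#' only and men only; warns when a group is smaller than the 15 subjects
#' usually considered the minimum for stable subject-independent results.
#'
#' @param table fused feature table (must carry a `gender` column).
#' @param classifier `"knn"` or `"qda"`.
#' @param seed RNG seed.
#' @return named list of three `classification_outcome`s
#'   (`all`, `women`, `men`).
#' @export
gender_split_classification <- function(table, classifier = c("knn", "qda"),
                                        seed = 1) {
  classifier <- match.arg(classifier)
  if (length(unique(table$gender)) < 2)
    stop("both genders must be present", call. = FALSE)
  lapply(setNames(c("all", "women", "men"), c("all", "women", "men")),
         function(g) classify(table, scheme = "SI", classifier = classifier,
                              gender_filter = g, seed = seed))
}
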