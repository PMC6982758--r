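# Simulated-annealing wrapper feature selection scored by cross-validated
# classifier F1.

#' Simulated-annealing configuration
#'
#' @param initial_temperature starting temperature in score (F1) units
#'   (default 0.1).
#' @param cooling_rate geometric per-step temperature multiplier in (0, 1)
#'   (default 0.95).
#' @param steps number of annealing steps (default 500).
#' @param min_size,max_size subset-size bounds (defaults 1 and the number of
#'   candidates).
#' @param classifier `"knn"` or `"qda"` objective.
#' @param cv_k folds of the stratified cross-validation objective (default 5).
#' @param seed RNG seed; the full run (initial state, proposals, acceptance,
#'   folds) is reproducible under it.
#' @return list of class `sa_config`.
#' @export
sa_config <- function(initial_temperature = 0.1, cooling_rate = 0.95,
                      steps = 500, min_size = 1, max_size = NULL,
                      classifier = c("knn", "qda"), cv_k = 5, seed = 1) {
  classifier <- match.arg(classifier)
  if (cooling_rate <= 0 || cooling_rate >= 1)
    stop_config("cooling_rate", "must be in (0, 1)")
  steps <- check_count(steps, "steps")
  min_size <- check_count(min_size, "min_size")
  if (!is.null(max_size)) {
    max_size <- check_count(max_size, "max_size")
    if (min_size > max_size) stop_config("min_size", "cannot exceed max_size")
  }
  structure(list(initial_temperature = check_pos(initial_temperature,
                                                 "initial_temperature"),
                 cooling_rate = cooling_rate, steps = steps,
                 min_size = min_size, max_size = max_size,
                 classifier = classifier, cv_k = cv_k,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "sa_config")
}

#' Cross-validated F1 of a feature subset
#'
#' Mean positive-class F1 over the provided fold assignment, the objective of
#' the annealing search. The same folds are reused for every subset evaluated
#' within a run, so subsets are compared without fold noise. An empty subset
#' scores 0 by convention.
#'
#' @param subset character vector of feature names.
#' @param features data frame of candidate feature columns.
#' @param labels class labels.
#' @param classifier `"knn"` or `"qda"`.
#' @param folds integer fold assignment per row.
#' @return mean F1 across folds.
#' @export
evaluate_subset <- function(subset, features, labels, classifier, folds) {
  if (length(subset) == 0) return(0)
  x <- as.matrix(features[, subset, drop = FALSE])
  scores <- vapply(sort(unique(folds)), function(f) {
    te <- folds == f
    trx <- x[!te, , drop = FALSE]; tex <- x[te, , drop = FALSE]
    mu <- colMeans(trx); sdv <- apply(trx, 2, sd)
    sdv[!is.finite(sdv) | sdv <= 0] <- 1
    trx <- sweep(sweep(trx, 2, mu), 2, sdv, `/`)
    tex <- sweep(sweep(tex, 2, mu), 2, sdv, `/`)
    pred <- predict_labels(classifier, trx, labels[!te], tex)
    f1_score(labels[te], pred)[["f1"]]
  }, numeric(1))
  mean(scores)
}

#' Select features by simulated annealing
#'
#' Metropolis search over feature subsets: the neighbour move flips one
#' randomly chosen feature in or out (re-proposed if it violates the size
#' bounds), better states are always accepted, worse ones with probability
#' `exp(delta / T)`, and the temperature decays geometrically. The best state
#' ever evaluated is returned; ties in best score are broken toward the
#' smaller subset.
#'
#' @param features data frame of candidate feature columns (>= 2 columns).
#' @param labels class labels (both classes present).
#' @param config an [sa_config()].
#' @param groups optional grouping vector (e.g. subject ids); folds are then
#'   group-disjoint, giving a subject-independent objective.
#' @return list of class `selection_result`: `selected` (feature names),
#'   `best_score`, `trace` (data frame per step: temperature, proposal score,
#'   accepted flag, current score, running best), `config`.
#' @export
anneal_select <- function(features, labels, config = sa_config(),
                          groups = NULL) {
  stopifnot(inherits(config, "sa_config"))
  cand <- names(features)
  if (length(cand) < 2)
    stop("at least 2 candidate features are required", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("labels must contain both classes", call. = FALSE)
  max_size <- config$max_size %||% length(cand)
  with_seed(derive_seed(config$seed, 7), {
    folds <- if (is.null(groups)) {
      grouped_stratified_folds(seq_along(labels), labels, config$cv_k)
    } else {
      g <- unique(groups)
      fold_of <- setNames(rep_len(seq_len(config$cv_k), length(g))[
        sample(length(g))], g)
      unname(fold_of[as.character(groups)])
    }
    cache <- new.env(parent = emptyenv())
    score_of <- function(state) {
      key <- paste(which(state), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <- evaluate_subset(cand[state], features, labels, config$classifier,
                           folds)
      cache[[key]] <- v
      v
    }
    state <- rep(FALSE, length(cand))
    state[sample(length(cand), max(config$min_size,
                                   min(max_size, length(cand) %/% 2)))] <- TRUE
    cur <- score_of(state)
    best <- cur; best_state <- state
    temp <- config$initial_temperature
    trace <- vector("list", config$steps)
    trace[[1]] <- data.frame(step = 1L, temperature = temp,
                             proposal_score = cur, accepted = TRUE,
                             current_score = cur, best_score = best)
    # step 1 is the evaluation of the initial state; proposals start at 2
    for (step in seq_len(config$steps)[-1]) {
      prop <- state
      repeat {
        flip <- sample(length(cand), 1)
        prop <- state; prop[flip] <- !prop[flip]
        sz <- sum(prop)
        if (sz >= config$min_size && sz <= max_size) break
      }
      sc <- score_of(prop)
      delta <- sc - cur
      accepted <- delta >= 0 || runif(1) < exp(delta / temp)
      if (accepted) { state <- prop; cur <- sc }
      if (cur > best || (cur == best && sum(state) < sum(best_state))) {
        best <- cur; best_state <- state
      }
      trace[[step]] <- data.frame(step = step, temperature = temp,
                                  proposal_score = sc, accepted = accepted,
                                  current_score = cur, best_score = best)
      temp <- temp * config$cooling_rate
    }
    structure(list(selected = cand[best_state], best_score = best,
                   trace = do.call(rbind, trace), config = config),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("simulated annealing (%s): best f1 = %.3f with %d features:\n  %s\n",
              toupper(x$config$classifier), x$best_score, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
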