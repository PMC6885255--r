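# Feature selection: traditional single-model recursive feature elimination
# (RFE) and multi-model RFE (mmRFE).
#
# mmRFE lets every model rank the surviving features by importance, sums
# each feature's rank position across models into a composite score,
# removes the composite-least-important features, and records every model's
# cross-validated accuracy at each iteration. The selected subset is the
# recorded iteration where all models clear the accuracy threshold and the
# minimum per-model accuracy is maximal.

#' Feature importance ranking of one model
#'
#' Linear models (LR, linear SVM) rank by the mean over classes of the
#' absolute standardized coefficient (features are z-scored before the
#' fit); tree ensembles (RF, GBDT) rank by impurity/gain importance.
#' Importance ties keep the features' column order in the table.
#'
#' @param config A [model_config()] (or a model id string).
#' @param table Feature table (`case_id`, `label`, feature columns).
#' @param features Optional feature subset to rank.
#' @return An `importance_ranking`: `model_id`, `labels`
#'   (importance-descending), `importance` (named scores), `position`
#'   (named 0-based rank positions, 0 = most important).
#' @export
model_importance <- function(config, table, features = NULL) {
  if (is.character(config)) config <- model_config(config)
  xy <- table_xy(table, features)
  if (ncol(xy$x) < 2) abort("need >= 2 features", "selection_error")
  if (length(unique(xy$y)) < 2) abort("need >= 2 classes", "selection_error")
  set.seed(config$seed)
  imp <- switch(config$model_id,
    lr = {
      fit <- fit_classifier(config, xy$x, xy$y)
      cf <- stats::coef(fit$model)
      if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list(NULL, names(cf)))
      cf <- cf[, setdiff(colnames(cf), "(Intercept)"), drop = FALSE]
      colMeans(abs(cf))[colnames(xy$x)]
    },
    svm = {
      sc <- scale_train(xy$x)
      ws <- vapply(levels(xy$y), function(cl) {
        yk <- factor(ifelse(xy$y == cl, cl, "rest"), levels = c(cl, "rest"))
        m <- e1071::svm(sc$x, yk, kernel = "linear", cost = config$cost,
                        scale = FALSE)
        abs(as.numeric(t(m$coefs) %*% m$SV))
      }, numeric(ncol(xy$x)))
      stats::setNames(rowMeans(ws), colnames(xy$x))
    },
    rf = {
      fit <- fit_classifier(config, xy$x, xy$y)
      randomForest::importance(fit$model)[colnames(xy$x), "MeanDecreaseGini"]
    },
    gbdt = {
      fit <- fit_classifier(config, xy$x, xy$y)
      it <- xgboost::xgb.importance(model = fit$model)
      stats::setNames(it$Gain[match(colnames(xy$x), it$Feature)], colnames(xy$x))
    },
    abort("importance is defined for lr, svm, rf, gbdt", "selection_error"))
  imp[is.na(imp)] <- 0                 # features never used by a tree model
  if (any(!is.finite(imp))) abort("non-finite importances", "selection_error")
  ord <- order(-imp)                   # stable: ties keep column order
  structure(list(model_id = config$model_id,
                 labels = colnames(xy$x)[ord],
                 importance = imp,
                 position = stats::setNames(order(ord) - 1L, colnames(xy$x)),
                 original_order = colnames(xy$x)),
            class = "importance_ranking")
}

#' Composite rank across several model rankings
#'
#' Each feature's 0-based positions are summed over the models; features
#' are returned sorted by ascending composite score (lower = more
#' important). Ties are broken by the best single-model position, then by
#' the features' column order in the table.
#'
#' @param rankings List of `importance_ranking` objects over one feature set.
#' @return Character vector of feature labels, most important first.
#' @export
composite_rank <- function(rankings) {
  sets <- lapply(rankings, function(r) sort(r$labels))
  if (!all(vapply(sets, identical, logical(1), sets[[1]])))
    abort("rankings cover different feature sets", "selection_error")
  feats <- rankings[[1]]$original_order
  score <- rowSums(vapply(rankings, function(r) r$position[feats],
                          numeric(length(feats))))
  best <- apply(vapply(rankings, function(r) r$position[feats],
                       numeric(length(feats))), 1, min)
  feats[order(score, best, seq_along(feats))]
}

resolve_step <- function(step, nfeat) {
  k <- if (step < 1) ceiling(step * nfeat) else round(step)
  max(1L, min(as.integer(k), nfeat - 1L))
}

#' Single-model recursive feature elimination
#'
#' Iteratively fits the model on the surviving features, records its
#' cross-validated accuracy, and removes the `step` least-important
#' features until one feature remains.
#'
#' @param config A [model_config()] (or model id string).
#' @param table Feature table.
#' @param step Features removed per iteration; values < 1 are treated as a
#'   fraction of the surviving set.
#' @param cv A [cv_scheme()].
#' @return An `elimination_trace`: list of iterations, each with `features`
#'   (surviving set), `accuracy`, and `removed`.
#' @export
rfe <- function(config, table, step = 1, cv = cv_scheme()) {
  if (is.character(config)) config <- model_config(config)
  current <- setdiff(names(table), c("case_id", "label"))
  if (length(current) < 2) abort("need >= 2 features", "selection_error")
  trace <- list()
  while (length(current) > 1) {
    rank <- model_importance(config, table, features = current)
    acc <- crossval_evaluate(config, table, cv, features = current)$accuracy
    k <- resolve_step(step, length(current))
    removed <- rev(rank$labels)[seq_len(k)]
    trace[[length(trace) + 1L]] <- list(features = current, accuracy = acc,
                                        removed = removed)
    current <- setdiff(current, removed)
  }
  structure(list(model_id = config$model_id, iterations = trace),
            class = "elimination_trace")
}

#' Multi-model recursive feature elimination (mmRFE)
#'
#' Per iteration every model ranks all surviving features, the rank
#' positions are summed into a composite order, every model's CV accuracy
#' on the surviving set is recorded, and the composite-least-important
#' `step` features are removed. Candidate subsets are the iterations where
#' every model's accuracy reaches `theta`; among them the selected subset
#' maximizes the minimum per-model accuracy (ties: maximal mean accuracy,
#' then smallest subset).
#'
#' @param configs List of >= 2 [model_config()] objects (or model id
#'   strings).
#' @param table Feature table.
#' @param step Features removed per iteration (fraction if < 1).
#' @param cv A [cv_scheme()].
#' @param theta Accuracy threshold every model must reach (default 0.8).
#' @return An `mmrfe_result`: `trace` (iterations with `features`,
#'   `accuracy` named per model, `composite`, `removed`), `selected`
#'   (feature labels, or `NULL` when no iteration meets `theta`),
#'   `selected_iteration`, `candidates`, `best_available` (the max-min
#'   iteration regardless of `theta`), `theta`.
#' @export
mmrfe <- function(configs, table, step = 1, cv = cv_scheme(), theta = 0.8) {
  if (theta < 0) abort("theta must be >= 0", "selection_error")
  configs <- lapply(configs, function(cf)
    if (is.character(cf)) model_config(cf) else cf)
  if (length(configs) < 2) abort("mmRFE needs >= 2 models", "selection_error")
  ids <- vapply(configs, `[[`, character(1), "model_id")
  names(configs) <- ids
  current <- setdiff(names(table), c("case_id", "label"))
  if (length(current) < 2) abort("need >= 2 features", "selection_error")
  trace <- list()
  while (length(current) > 1) {
    rankings <- lapply(configs, model_importance, table = table, features = current)
    comp <- composite_rank(rankings)
    accs <- vapply(configs, function(cf)
      crossval_evaluate(cf, table, cv, features = current)$accuracy, numeric(1))
    k <- resolve_step(step, length(current))
    removed <- rev(comp)[seq_len(k)]
    trace[[length(trace) + 1L]] <- list(features = current, accuracy = accs,
                                        composite = comp, removed = removed)
    current <- setdiff(current, removed)
  }
  min_acc <- vapply(trace, function(it) min(it$accuracy), numeric(1))
  mean_acc <- vapply(trace, function(it) mean(it$accuracy), numeric(1))
  size <- vapply(trace, function(it) length(it$features), numeric(1))
  pick <- function(idx) {
    idx[order(-min_acc[idx], -mean_acc[idx], size[idx])][1]
  }
  best_avail <- pick(seq_along(trace))
  candidates <- which(vapply(trace, function(it) all(it$accuracy >= theta),
                             logical(1)))
  if (length(candidates) == 0) {
    sel_it <- NA_integer_
    selected <- NULL
  } else {
    sel_it <- pick(candidates)
    selected <- trace[[sel_it]]$features
  }
  structure(list(trace = trace, selected = selected,
                 selected_iteration = sel_it, candidates = candidates,
                 best_available = trace[[best_avail]]$features,
                 best_available_iteration = best_avail, theta = theta),
            class = "mmrfe_result")
}

#' Simulate a feature table with planted informative features
#'
#' Validation fixture for feature-selection studies: `n_informative`
#' features carry class-dependent means (drawn once per class, then
#' standardized so every informative feature's class means have standard
#' deviation exactly `effect` — each planted feature genuinely separates
#' classes), the remaining features are pure noise; all features have unit
#' within-class noise. Class counts follow largest-remainder rounding of
#' `class_proportions`.
#'
#' @param n Number of samples.
#' @param n_informative,n_noise Feature counts.
#' @param class_proportions Four class weights (default: the 183/241/143/70
#'   cohort imbalance).
#' @param effect Between-class effect size (SD of the class means).
#' @param seed Integer seed.
#' @return List: `table` (feature table with labels) and `informative`
#'   (planted feature labels).
#' @export
simulate_planted_features <- function(n = 640, n_informative = 10, n_noise = 50,
                                      class_proportions = c(183, 241, 143, 70) / 637,
                                      effect = 1.5, seed = 1) {
  set.seed(seed)
  counts <- allocate_class_counts(n, class_proportions)
  y <- rep(SUBTYPE_LEVELS, counts)
  y <- y[sample.int(n)]
  p <- n_informative + n_noise
  labels <- sprintf("feat_%02d", seq_len(p))
  informative <- labels[seq_len(n_informative)]
  mu <- matrix(stats::rnorm(4 * n_informative), 4, n_informative,
               dimnames = list(SUBTYPE_LEVELS, NULL))
  if (n_informative > 0) {
    mu <- apply(mu, 2, function(col) {
      s <- stats::sd(col)
      if (s < .Machine$double.eps) col else (col - mean(col)) / s * effect
    })
    mu <- matrix(mu, 4, n_informative, dimnames = list(SUBTYPE_LEVELS, NULL))
  }
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, labels))
  x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
    mu[match(y, SUBTYPE_LEVELS), , drop = FALSE]
  tab <- data.frame(case_id = sprintf("s_%04d", seq_len(n)), label = y,
                    x, stringsAsFactors = FALSE, check.names = FALSE)
  list(table = tab, informative = informative)
}
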