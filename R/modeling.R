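# Classification models, cross-validated evaluation and the majority-vote
# ensemble.
#
# Four classifiers are supported under short ids: "lr" (multinomial
# logistic regression with L2 weight decay), "svm" (linear-kernel SVM with
# probability estimates), "rf" (random forest) and "gbdt" (gradient-boosted
# trees). Linear models consume fold-wise z-scored features; tree ensembles
# consume raw features.

MODEL_IDS <- c("lr", "svm", "rf", "gbdt")
# fixed tie-break priority for the ensemble (strongest first)
ENSEMBLE_PRIORITY <- c("gbdt", "svm", "rf", "lr")

#' Model configuration
#'
#' Hyperparameter defaults: LR uses L2 weight decay 1 (cost C = 1); SVM a
#' linear kernel with cost 1 and probability estimates; RF 500 trees; GBDT
#' 300 rounds with learning rate 0.1 and depth 3.
#'
#' @param model_id One of `"lr"`, `"svm"`, `"rf"`, `"gbdt"`, `"ensemble"`.
#' @param seed Integer seed fixed for any persisted run.
#' @param ... Hyperparameter overrides: `decay` (lr), `cost` (svm),
#'   `ntree` (rf), `nrounds`, `eta`, `max_depth` (gbdt).
#' @return A `model_config` object.
#' @export
model_config <- function(model_id, seed = 1, ...) {
  model_id <- match.arg(model_id, c(MODEL_IDS, "ensemble"))
  defaults <- list(decay = 1, cost = 1, ntree = 500,
                   nrounds = 300, eta = 0.1, max_depth = 3)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) abort(paste("unknown hyperparameters:", paste(bad, collapse = ", ")),
                         "model_config_error")
  defaults[names(over)] <- over
  structure(c(list(model_id = model_id, seed = as.integer(seed)), defaults),
            class = "model_config")
}

scale_train <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < .Machine$double.eps] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
}

scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# Fit one classifier. x: numeric matrix, y: factor. Returns an object with
# everything predict_classifier() needs.
fit_classifier <- function(config, x, y) {
  set.seed(config$seed)
  lev <- levels(y)
  fit <- switch(config$model_id,
    lr = {
      sc <- scale_train(x)
      df <- data.frame(sc$x, check.names = FALSE)
      df$.y <- y
      m <- nnet::multinom(.y ~ ., data = df, decay = config$decay,
                          trace = FALSE, maxit = 200, MaxNWts = 20000)
      list(model = m, scaler = sc)
    },
    svm = {
      sc <- scale_train(x)
      m <- e1071::svm(sc$x, y, kernel = "linear", cost = config$cost,
                      probability = TRUE, scale = FALSE)
      list(model = m, scaler = sc)
    },
    rf = {
      m <- randomForest::randomForest(x = x, y = y, ntree = config$ntree)
      list(model = m)
    },
    gbdt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      m <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = length(lev),
                      eta = config$eta, max_depth = config$max_depth,
                      nthread = 1),
        data = dtrain, nrounds = config$nrounds, verbose = 0)
      list(model = m)
    },
    abort("ensemble is fitted via fit_ensemble()", "model_config_error"))
  structure(c(fit, list(config = config, levels = lev,
                        features = colnames(x))),
            class = "subtyperad_fit")
}

# Class probabilities (n x K matrix, columns in level order) and labels.
predict_classifier <- function(fit, x) {
  x <- x[, fit$features, drop = FALSE]
  lev <- fit$levels
  prob <- switch(fit$config$model_id,
    lr = {
      p <- stats::predict(fit$model, newdata = data.frame(scale_apply(x, fit$scaler),
                                                          check.names = FALSE),
                          type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x), byrow = FALSE,
                                       dimnames = list(NULL, lev))
      p
    },
    svm = {
      pr <- stats::predict(fit$model, scale_apply(x, fit$scaler), probability = TRUE)
      attr(pr, "probabilities")[, lev, drop = FALSE]
    },
    rf = {
      stats::predict(fit$model, x, type = "prob")[, lev, drop = FALSE]
    },
    gbdt = {
      p <- stats::predict(fit$model, xgboost::xgb.DMatrix(x))
      if (is.null(dim(p)))
        p <- matrix(p, ncol = length(lev), byrow = TRUE)
      dimnames(p) <- list(NULL, lev)
      p
    })
  labels <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
  list(labels = labels, prob = prob)
}

#' Majority-vote ensemble prediction
#'
#' Each fitted model votes with its predicted label; the modal label wins.
#' Vote ties are broken by the highest mean predicted class probability
#' across models, residual ties by a fixed model-priority order (GBDT, SVM,
#' RF, LR).
#'
#' @param fits Named list of fitted models (as produced internally by
#'   [crossval_evaluate()] / `fit_classifier`), sharing one feature schema.
#' @param x Numeric feature matrix of the samples to classify.
#' @return Factor of predicted labels.
#' @export
ensemble_predict <- function(fits, x) {
  if (length(fits) < 2) abort("ensemble needs >= 2 fitted models", "model_config_error")
  feats <- lapply(fits, function(f) f$features)
  if (!all(vapply(feats, identical, logical(1), feats[[1]])))
    abort("fitted models do not share a feature schema", "model_config_error")
  lev <- fits[[1]]$levels
  preds <- lapply(fits, predict_classifier, x = x)
  n <- nrow(x)
  vote_mat <- vapply(preds, function(p) as.integer(p$labels), integer(n))
  if (n == 1) vote_mat <- matrix(vote_mat, nrow = 1)
  colnames(vote_mat) <- names(fits)
  mean_prob <- Reduce(`+`, lapply(preds, `[[`, "prob")) / length(preds)
  out <- majority_vote(vote_mat, mean_prob, length(lev),
                       intersect(ENSEMBLE_PRIORITY, names(fits)))
  factor(lev[out], levels = lev)
}

# Majority vote with the documented tie-breaks. vote_mat: n x n_models
# integer class indices with model-id column names; mean_prob: n x K mean
# class probabilities; priority: model ids, strongest first.
majority_vote <- function(vote_mat, mean_prob, n_classes, priority) {
  n <- nrow(vote_mat)
  out <- integer(n)
  for (i in seq_len(n)) {
    tallies <- tabulate(vote_mat[i, ], nbins = n_classes)
    top <- which(tallies == max(tallies))
    if (length(top) == 1) {
      out[i] <- top
      next
    }
    best <- top[mean_prob[i, top] == max(mean_prob[i, top])]
    if (length(best) == 1) {
      out[i] <- best
      next
    }
    out[i] <- best[1]
    for (m in priority) {
      v <- vote_mat[i, m]
      if (v %in% best) { out[i] <- v; break }
    }
  }
  out
}

#' Per-class classification report
#'
#' Pooled confusion matrix plus overall accuracy, per-class precision,
#' recall and F1, and their macro (unweighted) and weighted averages.
#' Metrics with zero denominators are reported as 0 with a warning.
#'
#' @param y_true,y_pred Equal-length label vectors (factors share levels).
#' @return A `class_report` list: `accuracy`, `per_class` (data.frame),
#'   `macro`, `weighted`, `confusion`.
#' @export
class_report <- function(y_true, y_pred) {
  if (length(y_true) == 0) abort("empty input", "report_error")
  if (length(y_true) != length(y_pred)) abort("length mismatch", "report_error")
  lev <- if (is.factor(y_true)) levels(y_true) else sort(unique(c(y_true, y_pred)))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  conf <- table(truth = y_true, prediction = y_pred)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  zero_warned <- FALSE
  safe_div <- function(a, b) {
    out <- ifelse(b == 0, 0, a / b)
    if (any(b == 0) && !zero_warned) {
      warning("zero denominator in per-class metrics; reported as 0")
      zero_warned <<- TRUE
    }
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(conf)
  per_class <- data.frame(class = lev, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.numeric(support))
  w <- support / sum(support)
  structure(list(
    accuracy = sum(tp) / sum(conf),
    per_class = per_class,
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    confusion = unclass(conf)
  ), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

# Split a feature table into x (matrix) and y (factor).
table_xy <- function(table, features = NULL) {
  feat_cols <- setdiff(names(table), c("case_id", "label"))
  if (!is.null(features)) {
    missing <- setdiff(features, feat_cols)
    if (length(missing)) abort(paste("features absent from table:",
                                     paste(missing, collapse = ", ")),
                               "model_config_error")
    feat_cols <- features
  }
  x <- as.matrix(table[, feat_cols, drop = FALSE])
  y <- factor(table$label)
  list(x = x, y = y)
}

#' Cross-validated evaluation of one model (or the ensemble)
#'
#' Out-of-fold predictions from all folds are pooled into a single
#' confusion matrix, from which the report is computed. Deterministic for a
#' fixed config seed and CV seed.
#'
#' @param config A [model_config()]; `model_id = "ensemble"` fits all four
#'   base models per fold and votes.
#' @param table Feature table (`case_id`, `label`, feature columns).
#' @param cv A [cv_scheme()].
#' @param features Optional feature-label subset to use.
#' @return A `class_report` (with the pooled predictions attached as
#'   attribute `"predictions"`).
#' @export
crossval_evaluate <- function(config, table, cv = cv_scheme(), features = NULL) {
  xy <- table_xy(table, features)
  folds <- cv_fold_ids(cv, xy$y)
  if (cv$type == "kfold") {
    per_fold <- table(xy$y, folds)
    if (any(per_fold == 0) && any(table(xy$y) >= cv$k))
      warning("some training folds miss a class; consider fewer folds")
  }
  pred <- factor(rep(NA_character_, length(xy$y)), levels = levels(xy$y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(xy$y[tr])) < length(levels(xy$y)))
      abort("a class is absent from a training fold; use stratified folds or fewer folds",
            "fold_error")
    if (config$model_id == "ensemble") {
      fits <- lapply(stats::setNames(MODEL_IDS, MODEL_IDS), function(mid) {
        cfg <- config; cfg$model_id <- mid
        fit_classifier(cfg, xy$x[tr, , drop = FALSE], droplevels(xy$y[tr]))
      })
      pred[!tr] <- as.character(ensemble_predict(fits, xy$x[!tr, , drop = FALSE]))
    } else {
      fit <- fit_classifier(config, xy$x[tr, , drop = FALSE], droplevels(xy$y[tr]))
      pred[!tr] <- as.character(predict_classifier(fit, xy$x[!tr, , drop = FALSE])$labels)
    }
  }
  rep <- class_report(xy$y, pred)
  attr(rep, "predictions") <- pred
  rep
}
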