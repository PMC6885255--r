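# Importance rankings, composite ranks, RFE and mmRFE.

fast_models <- function(seed = 1)
  lapply(c("lr", "svm", "rf", "gbdt"), model_config, seed = seed,
         ntree = 100, nrounds = 50)

test_that("every model ranks a perfectly separating feature first", {
  wins <- sapply(c("lr", "svm", "rf", "gbdt"), function(mid) {
    sum(vapply(1:5, function(s) {
      set.seed(s)
      n <- 120
      y <- rep(c("A", "B", "C", "D"), each = n / 4)
      sep <- as.numeric(factor(y)) * 3 + stats::rnorm(n, 0, 0.1)
      tab <- data.frame(case_id = as.character(1:n), label = y,
                        sep = sep, noise = stats::rnorm(n))
      cfg <- model_config(mid, seed = s, ntree = 100, nrounds = 50)
      model_importance(cfg, tab)$labels[1] == "sep"
    }, logical(1)))
  })
  expect_true(all(wins >= 4))   # majority of seeds for every model
})

test_that("duplicated columns tie-break by column order and reruns are identical", {
  set.seed(3)
  n <- 80
  y <- rep(c("A", "B", "C", "D"), each = n / 4)
  v <- as.numeric(factor(y)) + stats::rnorm(n, 0, 0.3)
  tab <- data.frame(case_id = as.character(1:n), label = y,
                    dup1 = v, dup2 = v)
  cfg <- model_config("rf", seed = 5)
  r1 <- model_importance(cfg, tab)
  r2 <- model_importance(cfg, tab)
  expect_identical(r1$labels, r2$labels)
  # exact importance ties resolve to table column order
  cfg_lr <- model_config("lr", seed = 5)
  rl <- model_importance(cfg_lr, tab)
  if (rl$importance["dup1"] == rl$importance["dup2"])
    expect_identical(rl$labels, c("dup1", "dup2"))
})

test_that("composite_rank sums positions with the documented tie-breaks", {
  mk <- function(id, labels) {
    structure(list(model_id = id, labels = labels,
                   importance = stats::setNames(rev(seq_along(labels)), labels),
                   position = stats::setNames(seq_along(labels) - 1L, labels),
                   original_order = c("f1", "f2", "f3")),
              class = "importance_ranking")
  }
  # single ranking: identity
  expect_identical(composite_rank(list(mk("m1", c("f2", "f3", "f1")))),
                   c("f2", "f3", "f1"))
  # hand-computed sums: f1 = 1, f2 = 1, f3 = 4
  out <- composite_rank(list(mk("m1", c("f1", "f2", "f3")),
                             mk("m2", c("f2", "f1", "f3"))))
  expect_identical(out[3], "f3")
  # exactly reversed rankings: all sums tie, best-position then column order
  out2 <- composite_rank(list(mk("m1", c("f1", "f2", "f3")),
                              mk("m2", c("f3", "f2", "f1"))))
  expect_identical(out2, c("f1", "f3", "f2"))
  # supplying the models in the other order must not change the result
  out3 <- composite_rank(list(mk("m2", c("f2", "f1", "f3")),
                              mk("m1", c("f1", "f2", "f3"))))
  expect_identical(out3[3], "f3")
  expect_error(composite_rank(list(mk("m1", c("f1", "f2", "f3")),
                                   mk("m2", c("f1", "f2", "f4")))),
               class = "selection_error")
})

test_that("rfe produces p - 1 records at step 1 and is deterministic", {
  sim <- simulate_planted_features(n = 120, n_informative = 3, n_noise = 5,
                                   class_proportions = rep(0.25, 4), seed = 4)
  cv <- cv_scheme("kfold", 4, seed = 2)
  cfg <- model_config("rf", seed = 2, ntree = 80)
  t1 <- rfe(cfg, sim$table, step = 1, cv = cv)
  expect_length(t1$iterations, 8 - 1)
  sizes <- vapply(t1$iterations, function(it) length(it$features), numeric(1))
  expect_identical(sizes, as.numeric(8:2))
  t2 <- rfe(cfg, sim$table, step = 1, cv = cv)
  expect_identical(t1, t2)
  accs <- vapply(t1$iterations, function(it) it$accuracy, numeric(1))
  expect_true(all(accs >= 0 & accs <= 1))
})

test_that("every removed feature had the worst composite score at its iteration", {
  sim <- simulate_planted_features(n = 120, n_informative = 3, n_noise = 5,
                                   class_proportions = rep(0.25, 4), seed = 6)
  res <- mmrfe(fast_models(2), sim$table, step = 1,
               cv = cv_scheme("kfold", 4, seed = 2), theta = 0.5)
  for (it in res$trace) {
    expect_identical(it$removed, it$composite[length(it$composite)])
    expect_true(all(it$removed %in% it$features))
  }
  sizes <- vapply(res$trace, function(it) length(it$features), numeric(1))
  expect_identical(sizes, as.numeric(length(res$trace[[1]]$features):2))
})

test_that("mmRFE with identical models reproduces the single-model trace", {
  sim <- simulate_planted_features(n = 120, n_informative = 3, n_noise = 5,
                                   class_proportions = rep(0.25, 4), seed = 8)
  cv <- cv_scheme("kfold", 4, seed = 3)
  cfg <- model_config("rf", seed = 3, ntree = 80)
  cfg2 <- cfg; cfg2$model_id <- "rf"
  single <- rfe(cfg, sim$table, step = 1, cv = cv)
  multi <- mmrfe(list(cfg, cfg2), sim$table, step = 1, cv = cv, theta = 0.5)
  expect_identical(lapply(single$iterations, `[[`, "features"),
                   lapply(multi$trace, `[[`, "features"))
  expect_identical(lapply(single$iterations, `[[`, "removed"),
                   lapply(multi$trace, `[[`, "removed"))
})

test_that("an unreachable threshold returns an explicit empty selection", {
  sim <- simulate_planted_features(n = 80, n_informative = 2, n_noise = 4,
                                   class_proportions = rep(0.25, 4), seed = 10)
  res <- mmrfe(list(model_config("lr", seed = 1), model_config("rf", seed = 1, ntree = 60)),
               sim$table, step = 2, cv = cv_scheme("kfold", 4, seed = 1),
               theta = 1.01)
  expect_null(res$selected)
  expect_true(is.na(res$selected_iteration))
  expect_gt(length(res$best_available), 0)
})
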