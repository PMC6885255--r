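# Classifiers, cross-validated evaluation, reports and the voting ensemble.

test_that("perfect predictions give all-ones metrics", {
  y <- factor(rep(c("A", "B", "C", "D"), 5))
  rep <- class_report(y, y)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$per_class$precision == 1))
  expect_true(all(rep$per_class$f1 == 1))
  expect_equal(unname(rep$macro["f1"]), 1)
})

test_that("majority-only predictions follow the analytic confusion matrix", {
  y <- factor(c(rep("A", 60), rep("B", 40)), levels = c("A", "B"))
  pred <- factor(rep("A", 100), levels = c("A", "B"))
  rep <- suppressWarnings(class_report(y, pred))
  a <- rep$per_class[rep$per_class$class == "A", ]
  b <- rep$per_class[rep$per_class$class == "B", ]
  expect_equal(a$precision, 0.6)
  expect_equal(a$recall, 1.0)
  expect_equal(b$recall, 0)
  expect_equal(rep$accuracy, 0.6)
})

test_that("report metrics equal direct confusion-matrix arithmetic", {
  set.seed(13)
  lev <- c("A", "B", "C", "D")
  for (i in 1:10) {
    y <- factor(sample(lev, 60, replace = TRUE), levels = lev)
    p <- factor(sample(lev, 60, replace = TRUE), levels = lev)
    rep <- suppressWarnings(class_report(y, p))
    for (cl in lev) {
      tp <- sum(y == cl & p == cl)
      fp <- sum(y != cl & p == cl)
      fn <- sum(y == cl & p != cl)
      pc <- rep$per_class[rep$per_class$class == cl, ]
      expect_equal(pc$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(pc$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
    }
    expect_equal(rep$accuracy, mean(y == p))
    expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
    expect_lte(unname(rep$macro["f1"]), max(rep$per_class$f1))
  }
})

test_that("majority vote equals the mode whenever the mode is unique", {
  # exhaustive: all vote patterns of 4 models over 4 classes
  grid <- expand.grid(m1 = 1:4, m2 = 1:4, m3 = 1:4, m4 = 1:4)
  prob <- matrix(0.25, 1, 4)
  for (r in seq_len(nrow(grid))) {
    votes <- matrix(as.integer(grid[r, ]), 1, 4,
                    dimnames = list(NULL, c("gbdt", "svm", "rf", "lr")))
    tallies <- tabulate(votes, nbins = 4)
    got <- subtyperad:::majority_vote(votes, prob, 4, c("gbdt", "svm", "rf", "lr"))
    if (sum(tallies == max(tallies)) == 1) {
      expect_equal(got, which.max(tallies))
    } else {
      # all-equal mean probabilities: the priority model's vote must win
      top <- which(tallies == max(tallies))
      expect_true(got %in% top)
      prio_vote <- votes[1, c("gbdt", "svm", "rf", "lr")]
      expect_equal(got, prio_vote[min(which(prio_vote %in% top))][[1]])
    }
  }
})

test_that("vote ties break toward the higher mean class probability", {
  votes <- matrix(c(1L, 1L, 2L, 2L), 1, 4,
                  dimnames = list(NULL, c("gbdt", "svm", "rf", "lr")))
  prob <- matrix(c(0.2, 0.5, 0.2, 0.1), 1, 4)
  expect_equal(subtyperad:::majority_vote(votes, prob, 4,
                                          c("gbdt", "svm", "rf", "lr")), 2L)
})

test_that("leave-one-out pools exactly n predictions", {
  sim <- simulate_planted_features(n = 40, n_informative = 2, n_noise = 2,
                                   class_proportions = rep(0.25, 4), seed = 3)
  rep <- crossval_evaluate(model_config("lr", seed = 1), sim$table,
                           cv = cv_scheme("loo"))
  pred <- attr(rep, "predictions")
  expect_length(pred, 40)
  expect_false(anyNA(pred))
  expect_equal(sum(rep$confusion), 40)
})

test_that("cross-validated evaluation is deterministic under fixed seeds", {
  sim <- simulate_planted_features(n = 80, n_informative = 3, n_noise = 4,
                                   class_proportions = rep(0.25, 4), seed = 5)
  cv <- cv_scheme("kfold", 4, seed = 9)
  for (mid in c("lr", "svm", "rf", "gbdt")) {
    cfg <- model_config(mid, seed = 7, ntree = 80, nrounds = 40)
    r1 <- crossval_evaluate(cfg, sim$table, cv)
    r2 <- crossval_evaluate(cfg, sim$table, cv)
    expect_identical(r1$confusion, r2$confusion)
  }
})

test_that("well-separated classes are classified nearly perfectly", {
  sim <- simulate_planted_features(n = 160, n_informative = 6, n_noise = 6,
                                   effect = 3, seed = 11)
  cv <- cv_scheme("kfold", 5, seed = 1)
  rep <- crossval_evaluate(model_config("ensemble", seed = 1, ntree = 100,
                                        nrounds = 50), sim$table, cv)
  expect_gte(rep$accuracy, 0.95)
})

test_that("a class absent from a training fold raises a fold error", {
  sim <- simulate_planted_features(n = 40, n_informative = 2, n_noise = 2,
                                   class_proportions = rep(0.25, 4), seed = 3)
  tab <- sim$table[c(which(sim$table$label != "D"),
                     which(sim$table$label == "D")[1]), ]
  suppressWarnings(
    expect_error(crossval_evaluate(model_config("lr"), tab,
                                   cv = cv_scheme("kfold", 5, seed = 1)),
                 class = "fold_error"))
})
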