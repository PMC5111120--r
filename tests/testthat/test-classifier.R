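# SVM grid search, CV evaluation and metrics

blobs <- function(n = 100, sep = 6, seed = 1) {
  with_seed(seed, {
    y <- rep(c(-1, 1), each = n / 2)
    X <- cbind(x1 = rnorm(n) + sep * (y == 1),
               x2 = rnorm(n) - sep * (y == 1))
    list(X = X, y = y)
  })
}

small_grid <- data.frame(C = c(1, 1, 100), gamma = c(0.01, 0.5, 0.01))

test_that("the (C, gamma) grid has the canonical 110 pairs", {
  g <- svm_grid()
  expect_equal(nrow(g), 110)
  expect_setequal(unique(g$C), 2^seq(-5, 15, 2))
  expect_setequal(unique(g$gamma), 2^seq(3, -15, -2))
})

test_that("min-max scaling maps train range to [-1,1], constants to 0", {
  tr <- cbind(a = c(0, 10, 5), b = rep(3, 3))
  te <- cbind(a = c(20, -10), b = c(3, 7))
  sc <- scale_features(tr, te)
  expect_equal(unname(sc$train[, "a"]), c(-1, 1, 0))
  expect_true(all(sc$train[, "b"] == 0))
  expect_equal(unname(sc$applied[, "a"]), c(3, -3))   # outside [-1,1] allowed
})

test_that("metric identities hold for a hand confusion matrix", {
  m <- classification_metrics(tp = 40, tn = 35, fp = 15, fn = 10)
  expect_equal(unname(m["Acc"]), 0.75)
  expect_equal(unname(m["Sen"]), 0.8)
  expect_equal(unname(m["Spe"]), 0.7)
  expect_equal(unname(m["Pre"]), 40 / 55, tolerance = 1e-12)
  mcc <- (40 * 35 - 15 * 10) / sqrt(55 * 50 * 50 * 45)
  expect_equal(unname(m["Mcc"]), mcc)
  expect_equal(round(unname(m["Pre"]), 3), 0.727)
  expect_equal(round(unname(m["Mcc"]), 3), 0.503)
  # vanishing denominators fall back to 0
  z <- classification_metrics(0, 10, 0, 0)
  expect_equal(unname(z[c("Sen", "Pre", "Mcc")]), c(0, 0, 0))
})

test_that("trapezoidal AUCs agree with pROC and are transform-invariant", {
  skip_if_not_installed("pROC")
  set.seed(30)
  y <- sample(c(-1, 1), 80, replace = TRUE)
  s <- rnorm(80) + (y == 1)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
  expect_equal(roc_auc(exp(s), y), roc_auc(s, y), tolerance = 1e-12)
  expect_true(pr_auc(s, y) >= 0 && pr_auc(s, y) <= 1)
  # perfect separation
  expect_equal(roc_auc(y, y), 1)
  expect_equal(pr_auc(y * 10, y), 1)
})

test_that("separable blobs give a perfect report; nulls sit near chance", {
  d <- blobs(n = 100)
  rep <- cv_evaluate(d$X, d$y, grid = small_grid, folds = 5, seed = 1)
  expect_equal(unname(rep$metrics["Acc"]), 1)
  expect_equal(unname(rep$metrics["Mcc"]), 1)
  expect_equal(rep$AUCR, 1)
  # shuffled labels: AUC around 0.5
  y_null <- with_seed(99, sample(d$y))
  rep0 <- cv_evaluate(d$X, y_null, grid = small_grid, folds = 5, seed = 1)
  expect_gt(rep0$AUCR, 0.3)
  expect_lt(rep0$AUCR, 0.7)
})

test_that("reports recompute from their own confusion counts and reproduce", {
  d <- blobs(n = 60, sep = 1.2, seed = 4)
  rep <- cv_evaluate(d$X, d$y, grid = small_grid, folds = 5, seed = 7)
  cc <- rep$counts
  expect_equal(rep$metrics,
               classification_metrics(cc["TP"], cc["TN"], cc["FP"], cc["FN"]),
               ignore_attr = TRUE)
  expect_equal(sum(cc), length(d$y))
  rep2 <- cv_evaluate(d$X, d$y, grid = small_grid, folds = 5, seed = 7)
  expect_identical(rep$metrics, rep2$metrics)
  expect_identical(rep$decision_values, rep2$decision_values)
  expect_error(cv_evaluate(d$X, rep(1, 60), grid = small_grid),
               "both classes")
})

test_that("stratified folds balance classes and respect the seed", {
  y <- rep(c(-1, 1), c(30, 70))
  folds <- stratified_folds(y, k = 10, seed = 3)
  expect_length(unlist(folds), 100)
  expect_false(anyDuplicated(unlist(folds)) > 0)
  for (f in folds) expect_equal(sum(y[f] == -1), 3)
  expect_identical(folds, stratified_folds(y, k = 10, seed = 3))
  expect_error(stratified_folds(rep(c(-1, 1), c(3, 97)), k = 10), "folds")
})

test_that("grid-search tie-break prefers smaller C then larger gamma", {
  d <- blobs(n = 60)   # several pairs reach Acc = 1
  grid <- data.frame(C = c(100, 1, 1), gamma = c(0.1, 0.01, 0.5))
  rep <- cv_evaluate(d$X, d$y, grid = grid, folds = 5, seed = 1)
  expect_equal(rep$C, 1)
  expect_equal(rep$gamma, 0.5)
})

test_that("the optimal subset maximises accuracy with ties to fewer features", {
  set.seed(40)
  n <- 80
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(signal = y + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("n", 1:9))))
  subsets <- list(`1` = "signal", `3` = c("signal", "n1", "n2"),
                  `2noise` = c("n1", "n2"))
  pick <- select_optimal_subset(subsets, X, y, grid = small_grid,
                                folds = 5, seed = 2)
  accs <- vapply(pick$all_reports, function(r) unname(r$metrics["Acc"]),
                 numeric(1))
  expect_equal(unname(pick$report$metrics["Acc"]), max(accs))
  expect_true("signal" %in% pick$features)
  # explicit tie: identical subsets of different size
  tie <- list(small = "signal", big = c("signal", "signal2" = "signal"))
  tie$big <- c("signal", "signal")  # duplicated column content
  X2 <- cbind(X, signal2 = X[, "signal"])
  pick2 <- select_optimal_subset(list(s5 = "signal",
                                      s10 = c("signal", "signal2")),
                                 X2, y, grid = small_grid, folds = 5, seed = 2)
  if (unname(pick2$all_reports$s5$metrics["Acc"]) ==
      unname(pick2$all_reports$s10$metrics["Acc"]))
    expect_equal(pick2$size, 1)
})

test_that("nested mRMR selection restricts each fold to top features", {
  set.seed(50)
  n <- 60
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(sig = y + rnorm(n, sd = 0.2),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("z", 1:20))))
  rep <- cv_evaluate(X, y, grid = small_grid, folds = 5, seed = 1,
                     n_features = 3)
  expect_equal(rep$subset_size, 3)
  expect_gt(unname(rep$metrics["Acc"]), 0.8)
})
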