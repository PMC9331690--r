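test_that("robust scaling uses training medians and IQRs only", {
  tr <- cbind(a = c(1, 2, 3, 4, 5), b = rep(7, 5))
  te <- cbind(a = c(3, 30), b = c(7, 9))
  sc <- robust_scale_fit_transform(tr, te)
  expect_equal(unname(sc$train[, "a"]), c(-1, -0.5, 0, 0.5, 1))
  expect_equal(unname(sc$train[, "b"]), rep(0, 5))  # centered, not divided
  expect_equal(unname(sc$other[, "a"]), c(0, 13.5))
  expect_equal(unname(sc$other[, "b"]), c(0, 2))
  # applying the fitted params elsewhere never re-estimates them
  again <- robust_scale_apply(sc$params, te)
  expect_identical(again, sc$other)
  expect_error(robust_scale_fit_transform(tr[1, , drop = FALSE]), "2 training")
})

test_that("grid search covers 144 candidates and solves separable data", {
  set.seed(8)
  n <- 60
  x <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  x <- x + 5 * cbind(y, y)  # widely separable
  mod <- grid_search_svm(x, y, seed = 4)
  expect_equal(nrow(mod$grid), 4 * 6 * 6)
  expect_true(all(is.finite(mod$grid$cv_auc)))
  expect_equal(mod$cv_auc, 1)
  ev <- evaluate_svm(mod, x, y, x, y)
  expect_equal(ev$auc, 1)
  expect_equal(ev$test_accuracy, 1)
  expect_error(grid_search_svm(x, rep(1, n)), "both classes")
})

test_that("label-shuffled cohorts score at chance", {
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 200
    x <- matrix(rnorm(n * 2), n)
    y <- rbinom(n, 1, 0.5)
    tr <- seq_len(160); te <- 161:n
    if (length(unique(y[te])) < 2) y[te[1:2]] <- c(0, 1)
    sc <- robust_scale_fit_transform(x[tr, ], x[te, ])
    mod <- grid_search_svm(sc$train, y[tr], seed = seed)
    evaluate_svm(mod, sc$train, y[tr], sc$other, y[te])$auc
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("evaluation metrics are consistent with the confusion counts", {
  set.seed(3)
  n <- 80
  x <- matrix(rnorm(n * 3), n)
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.8) > 0)
  tr <- 1:60; te <- 61:80
  mod <- grid_search_svm(x[tr, ], y[tr], seed = 1)
  ev <- evaluate_svm(mod, x[tr, ], y[tr], x[te, ], y[te])
  cm <- ev$confusion
  expect_equal(ev$test_accuracy, (cm[["tp"]] + cm[["tn"]]) / sum(cm),
               tolerance = 1e-12)
  expect_equal(ev$precision, cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]),
               tolerance = 1e-12)
  expect_equal(ev$recall, cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
               tolerance = 1e-12)
  expect_true(all(unlist(ev[c("train_accuracy", "test_accuracy", "auc",
                              "precision", "recall")]) >= 0))
  expect_error(evaluate_svm(mod, x[tr, ], y[tr], x[te, ], rep(1, 20)),
               "lacks a class")
})

test_that("fold assignment is stratified, seeded and test-independent", {
  y <- rep(c(0, 1), c(30, 70))
  f1 <- strokefeat:::stratified_folds(y, 5, seed = 2)
  f2 <- strokefeat:::stratified_folds(y, 5, seed = 2)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_equal(sum(y == 0 & f1 == k), 6)
    expect_equal(sum(y == 1 & f1 == k), 14)
  }
  # the fitted scaler and selected model never see test rows
  set.seed(10)
  x <- matrix(rnorm(100 * 4), 100)
  y <- rbinom(100, 1, 0.5)
  sc1 <- robust_scale_fit_transform(x[1:80, ], x[81:100, ])
  sc2 <- robust_scale_fit_transform(x[1:80, ], x[81:90, ])
  expect_identical(sc1$params, sc2$params)
  m1 <- grid_search_svm(sc1$train, y[1:80], seed = 7)
  m2 <- grid_search_svm(sc2$train, y[1:80], seed = 7)
  expect_identical(m1[c("kernel", "C", "gamma", "cv_auc")],
                   m2[c("kernel", "C", "gamma", "cv_auc")])
})
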