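test_that("AUC is the Mann-Whitney pair-counting estimator", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)  # 3 wins, 1 loss of 4 pairs
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)  # all ties
  set.seed(1)
  s <- rnorm(1000); y <- rbinom(1000, 1, 0.5)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the ROC curve is monotone and its trapezoid equals the estimator", {
  set.seed(7)
  for (rep in 1:5) {
    s <- rnorm(60); y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_equal(tail(r$curve$fpr, 1), 1)
    expect_equal(tail(r$curve$tpr, 1), 1)
    trap <- sum(diff(r$curve$fpr) *
                  (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("DeLong handles identity, symmetry and degeneracy", {
  set.seed(2)
  y <- rbinom(100, 1, 0.5)
  s <- rnorm(100) + y
  d0 <- delong_test(s, s, y)
  expect_equal(d0$p_two_sided, 1)
  expect_equal(d0$auc_a, d0$auc_b)
  s2 <- rnorm(100)
  d1 <- delong_test(s, s2, y)
  d2 <- delong_test(s2, s, y)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p_two_sided, d2$p_two_sided)
  expect_gte(d1$var_diff, 0)
})

test_that("DeLong matches the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:20) {
    n <- 80
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    sa <- rnorm(n) + 0.8 * y * runif(1)
    sb <- rnorm(n) + 0.8 * y * runif(1)
    mine <- delong_test(sa, sb, y)
    ref <- pROC::roc.test(
      pROC::roc(y, sa, quiet = TRUE, direction = "<", levels = c(0, 1)),
      pROC::roc(y, sb, quiet = TRUE, direction = "<", levels = c(0, 1)),
      method = "delong")
    expect_equal(mine$p_two_sided, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("DeLong agrees with a 2000-replicate paired bootstrap", {
  set.seed(21)
  worst <- 0
  for (rep in 1:20) {
    n <- 120
    y <- rbinom(n, 1, 0.5)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
    sa <- rnorm(n) + 0.9 * y
    sb <- rnorm(n) + runif(1, 0, 0.9) * y
    p_d <- delong_test(sa, sb, y)$p_two_sided
    p_b <- bootstrap_delong_p(sa, sb, y, reps = 2000, seed = rep)
    worst <- max(worst, abs(p_d - p_b))
  }
  expect_lt(worst, 0.05)
})

test_that("DeLong has power against informative classifiers and nominal size", {
  set.seed(31)
  rejections <- vapply(1:100, function(i) {
    y <- rbinom(500, 1, 0.5)
    informative <- rnorm(500) + y
    noise <- rnorm(500)
    delong_test(informative, noise, y)$p_two_sided < 0.01
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
  null_rej <- vapply(1:200, function(i) {
    y <- rbinom(200, 1, 0.5)
    delong_test(rnorm(200), rnorm(200), y)$p_two_sided < 0.05
  }, TRUE)
  expect_gt(mean(null_rej), 0.01)
  expect_lt(mean(null_rej), 0.10)
})

test_that("Kernel SHAP is exact for linear models and always locally accurate", {
  set.seed(5)
  m <- 6
  w <- rnorm(m)
  fn <- function(X) as.numeric(as.matrix(X) %*% w)
  bg <- matrix(rnorm(40 * m), 40)
  x <- rnorm(m)
  sh <- kernel_shap(fn, x, bg, n_samples = 256, seed = 1)
  expect_equal(unname(sh$phi), w * (x - colMeans(bg)), tolerance = 1e-8)
  expect_equal(sum(sh$phi), sh$fx - sh$base_value, tolerance = 1e-6)
  # nonlinear model, sampled coalitions: local accuracy must still hold
  fn2 <- function(X) sin(as.matrix(X)[, 1]) + as.matrix(X)[, 2]^2 *
    as.matrix(X)[, 3]
  x2 <- rnorm(12); bg2 <- matrix(rnorm(25 * 12), 25)
  sh2 <- kernel_shap(function(X) fn2(cbind(X, 0)), x2, bg2,
                     n_samples = 600, seed = 2)
  expect_equal(sum(sh2$phi), sh2$fx - mean(fn2(cbind(bg2, 0))),
               tolerance = 1e-6)
  expect_error(kernel_shap(fn, x, bg, n_samples = 4), "n_samples")
})

test_that("Kernel SHAP with full enumeration equals exact Shapley values", {
  set.seed(6)
  m <- 8
  bg <- matrix(rnorm(15 * m), 15)
  x <- rnorm(m)
  fn <- function(X) {
    X <- as.matrix(X)
    X[, 1] * X[, 2] + tanh(X[, 3]) + 0.5 * X[, 4]^2 - X[, 5] * 0.3 +
      0.2 * X[, 6] * X[, 7] - 0.1 * X[, 8]
  }
  sh <- kernel_shap(fn, x, bg, n_samples = 2048, seed = 3)
  exact <- exact_shapley(fn, x, bg)
  expect_equal(unname(sh$phi), exact, tolerance = 1e-3)
})

test_that("importance ranking surfaces the dominant feature", {
  set.seed(9)
  fn <- function(X) 5 * as.matrix(X)[, 3] + 0.1 * as.matrix(X)[, 1]
  bg <- matrix(rnorm(20 * 5), 20)
  shaps <- lapply(1:4, function(i)
    kernel_shap(fn, rnorm(5), bg, n_samples = 64, seed = i))
  rep5 <- importance_report(shaps, paste0("f", 1:5), k = 3)
  expect_equal(rep5$feature[1], "f3")
  full <- importance_report(shaps, paste0("f", 1:5), k = 99)
  expect_equal(nrow(full), 5)
})
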