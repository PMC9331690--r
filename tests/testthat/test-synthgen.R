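small_spec <- cohort_spec(n_subjects = 4, grid = "small", seed = 7)

test_that("subject generation is a pure function of spec and seed", {
  a <- generate_volume(small_spec, 123)
  b <- generate_volume(small_spec, 123)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$outcome, b$outcome)
  c <- generate_volume(small_spec, 124)
  expect_false(identical(a$volume$data, c$volume$data))
  # lesion is one 26-connected component inside the brain
  lab <- strokefeat:::.cpp_cc_label(a$mask$data, dim(a$mask$data), 26L)
  expect_equal(max(lab), 1L)
})

test_that("homogeneous lesions are near-uniform and volumes are faithful", {
  for (v in c(5, 20, 80)) {
    s <- generate_volume(small_spec, 400 + v, h = 0, v_ml = v)
    les <- s$volume$data[s$mask$data == 1L]
    expect_lt(sd(les), 0.05 * mean(les))
    painted_ml <- sum(s$mask$data) * s$mask$spacing_mm^3 / 1000
    expect_lt(abs(painted_ml - v) / v, 0.15)
  }
  expect_error(generate_volume(small_spec, 1, v_ml = 5000), "grid too small")
})

test_that("outcome model reduces to a fair coin and saturates in beta0", {
  flat <- small_spec
  flat$beta0 <- 0; flat$beta_h <- 0; flat$beta_v <- 0; flat$label_noise_sd <- 0
  set.seed(1)
  draws <- generate_outcome(rep(0.5, 4000), rep(30, 4000), flat)
  expect_gt(mean(draws), 0.47)
  expect_lt(mean(draws), 0.53)
  sat <- flat; sat$beta0 <- 50
  set.seed(1)
  expect_true(all(generate_outcome(runif(200), runif(200, 5, 150), sat) == 1))
  expect_error(generate_outcome(1.5, 10, flat), "must lie")
})

test_that("heterogeneity dominates log-volume in the planted signal", {
  spec <- cohort_spec(n_subjects = 2000, grid = "small", seed = 1)
  set.seed(99)
  h <- rbeta(2000, 0.3, 0.3)
  v <- exp(runif(2000, log(5), log(150)))
  y <- generate_outcome(h, v, spec)
  expect_gt(mean(y[h < 0.2]), mean(y[h > 0.8]))  # P(favorable) decreasing in h
  expect_gt(abs(cor(h, y, method = "spearman")),
            abs(cor(log(v), y, method = "spearman")))
})

test_that("planted coefficients are recoverable by logistic regression", {
  spec <- cohort_spec(n_subjects = 200, grid = "small", seed = 1)
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    h <- rbeta(200, 0.3, 0.3)
    v <- exp(runif(200, log(5), log(150)))
    y <- generate_outcome(h, v, spec)
    fit <- suppressWarnings(glm(y ~ h + log(v), family = binomial()))
    b <- coef(fit)
    if (b[["h"]] < 0 && b[["log(v)"]] < 0 &&
        abs(b[["h"]]) > abs(b[["log(v)"]])) ok <- ok + 1
  }
  expect_gte(ok, 19)  # >= 95% of 20 seeds
})

test_that("split arithmetic reproduces the study counts", {
  sp <- split_cohort(seq_len(206), test_fraction = 0.2, seed = 3)
  expect_length(sp$test, 41)
  sp2 <- split_cohort(seq_len(316), test_fraction = 0.2, seed = 3)
  expect_length(sp2$train, 253)
  sp3 <- split_cohort(seq_len(10), test_fraction = 0.2, val_fraction = 0.1,
                      seed = 3)
  expect_equal(lengths(sp3[c("train", "val", "test")]),
               c(train = 7L, val = 1L, test = 2L))
  # disjoint and exhaustive
  expect_setequal(unlist(sp3), seq_len(10))
  expect_equal(anyDuplicated(unlist(sp3)), 0L)
  # stratification balances outcome rates
  y <- rep(c(0, 1), c(60, 140))
  sps <- split_cohort(seq_len(200), 0.2, seed = 5, labels = y)
  expect_equal(sum(y[sps$test]), 28)  # 140/200 * 40
  expect_error(split_cohort(1:3, test_fraction = 0.9, val_fraction = 0.2))
  cnt <- split_counts(seq_len(206), 144, 21, 41, seed = 1)
  expect_equal(lengths(cnt), c(train = 144L, val = 21L, test = 41L))
})

test_that("heterogeneity monotonically drives GLSZM large-area emphasis", {
  lahgle <- function(sub) {
    nv <- white_stripe_normalize(sub$volume)
    d <- discretize(nv, sub$mask)
    P <- build_glszm(d)
    large_area_emphases(P, attr(P, "N_z"))[["LAHGLE"]]
  }
  hi <- lo <- numeric(20)
  for (s in 1:20) {
    hi[s] <- lahgle(generate_volume(small_spec, 7000 + s, h = 0.9, v_ml = 40))
    lo[s] <- lahgle(generate_volume(small_spec, 7000 + s, h = 0.1, v_ml = 40))
  }
  expect_true(all(hi > lo))
  # rank correlation with h at fixed volume
  hs <- seq(0.05, 0.95, length.out = 15)
  vals <- vapply(seq_along(hs), function(i)
    lahgle(generate_volume(small_spec, 7100 + i, h = hs[i], v_ml = 40)), 0)
  expect_gt(cor(hs, vals, method = "spearman"), 0.6)
})

test_that("cohorts round-trip through NIfTI and CSV", {
  spec <- cohort_spec(n_subjects = 6, grid = "small", seed = 5)
  cohort <- generate_cohort(spec)
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("id", "outcome", "h_true", "v_true_ml", "split"))
  v <- read_volume(file.path(dir, paste0(tab$id[1], "_dwi.nii.gz")))
  m <- read_mask(file.path(dir, paste0(tab$id[1], "_mask.nii.gz")))
  expect_equal(v$spacing_mm, 6)
  expect_equal(v$data, cohort$subjects[[1]]$volume$data, tolerance = 1e-6)
  expect_identical(m$data, cohort$subjects[[1]]$mask$data)
  unlink(dir, recursive = TRUE)
})
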