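test_that("white-stripe maps the stripe to zero mean and unit sd", {
  set.seed(2)
  arr <- array(0, c(20, 20, 20))
  bm <- array(FALSE, dim(arr)); bm[3:18, 3:18, 3:18] <- TRUE
  arr[bm] <- rnorm(sum(bm), 100, 10)
  nv <- white_stripe_normalize(vol3d(arr, 1), bm)
  ws <- attr(nv, "white_stripe")
  z <- nv$data[bm]
  qs <- quantile(arr[bm], ecdf(arr[bm])(ws$mode) + c(-0.05, 0.05))
  stripe <- z[arr[bm] >= qs[1] & arr[bm] <= qs[2]]
  expect_lt(abs(mean(stripe)), 0.05)
  expect_gt(sd(stripe), 0.9); expect_lt(sd(stripe), 1.1)
  expect_true(all(nv$data[!bm] == 0))
})

test_that("normalization is affine-invariant and idempotent", {
  s <- generate_volume(cohort_spec(4, grid = "small", seed = 3), 42)
  v <- s$volume
  n1 <- white_stripe_normalize(v)
  v2 <- vol3d(ifelse(v$data != 0, 3.7 * v$data + 11, 0), v$spacing_mm)
  n2 <- white_stripe_normalize(v2, v$data != 0)
  expect_lt(max(abs(n1$data - n2$data)), 1e-6)
  n3 <- white_stripe_normalize(n1, v$data != 0)
  expect_lt(max(abs(n3$data - n1$data)), 1e-6)
})

test_that("the dominant mode of a bimodal brain is found within 2 units", {
  set.seed(5)
  x <- c(rnorm(6000, 80, 5), rnorm(14000, 120, 5))
  arr <- array(0, c(30, 30, 30)); bm <- array(FALSE, dim(arr))
  bm[seq_len(20000)] <- TRUE; arr[bm] <- x
  nv <- white_stripe_normalize(vol3d(arr, 1), bm)
  detected <- attr(nv, "white_stripe")$mode
  # brute-force histogram scan of the same sample
  br <- seq(min(x) - 0.5, max(x) + 0.5, by = 0.5)
  hh <- hist(x, breaks = br, plot = FALSE)
  oracle_mode <- hh$mids[which.max(hh$counts)]
  expect_lt(abs(detected - oracle_mode), 2)
  expect_lt(abs(detected - 120), 2)
})

test_that("degenerate inputs are rejected", {
  arr <- array(1, c(5, 5, 5))
  expect_error(white_stripe_normalize(vol3d(arr, 1)), "degenerate")
  expect_error(white_stripe_normalize(vol3d(array(0, c(5, 5, 5)), 1)), "empty")
})

test_that("resampling to coarser spacing is shape- and mass-consistent", {
  const <- vol3d(array(2.5, c(10, 12, 14)), 1)
  rc <- resample_isotropic(const, 2)
  expect_equal(dim(rc$data), c(5, 6, 7))
  expect_true(all(abs(rc$data - 2.5) < 1e-12))
  big <- vol3d(array(0, c(181, 217, 181)), 1)
  expect_equal(dim(resample_isotropic(big, 3)$data), c(61, 73, 61))
  # integral of a smooth blob is conserved within 2%
  g <- seq(-3, 3, length.out = 48)
  blob <- array(exp(-outer(outer(g^2, g^2, `+`), g^2, `+`) / 2), c(48, 48, 48))
  bv <- vol3d(blob, 1)
  r <- resample_isotropic(bv, 2.4)
  m0 <- sum(bv$data) * 1^3
  m1 <- sum(r$data) * 2.4^3
  expect_lt(abs(m1 - m0) / m0, 0.02)
  expect_error(resample_isotropic(bv, 0.5), "upsampling")
})

test_that("padding to the autoencoder grid is symmetric and exactly invertible", {
  v <- vol3d(array(rnorm(61 * 73 * 61), c(61, 73, 61)), 3)
  p <- pad_to_cae_grid(v)
  expect_equal(dim(p$data), c(64, 80, 64))
  expect_equal(p$origin_offset, c(1L, 3L, 1L))
  expect_identical(crop_from_cae_grid(p, dim(v$data))$data, v$data)
  z <- pad_to_cae_grid(vol3d(array(0, c(10, 10, 10)), 3), c(16, 16, 16))
  expect_true(all(z$data == 0))
  expect_error(pad_to_cae_grid(vol3d(array(0, c(70, 70, 70)), 3)), "larger")
  # padding never alters nonzero voxels
  expect_equal(sum(p$data != 0), sum(v$data != 0))
})
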