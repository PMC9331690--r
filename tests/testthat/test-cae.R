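test_that("architecture shape tables match the stride-2 arithmetic", {
  full <- cae_config("full")
  st <- cae_shape_table(full)
  expect_equal(st$output_shape[st$layer == "enc_conv4"], "4x5x4x128")
  expect_equal(st$output_shape[st$layer == "flatten"], "10240")
  expect_equal(st$output_shape[st$layer == "latent"], "100")
  expect_equal(st$output_shape[st$layer == "dec_extra3"], "64x80x64x1")
  mini <- cae_config("mini")
  stm <- cae_shape_table(mini)
  expect_equal(stm$output_shape[stm$layer == "reshape"], "2x3x2x64")
  expect_equal(stm$output_shape[stm$layer == "dec_extra3"], "32x48x32x1")
  expect_error(cae_config("mini", input_shape = c(32, 40, 32)), "divisible")
})

test_that("convolution gradients agree with finite differences", {
  set.seed(4)
  for (case in list(list(k = 3, s = 1L, plo = c(1L, 1L, 1L), phi = c(1L, 1L, 1L)),
                    list(k = 4, s = 2L, plo = c(1L, 1L, 1L), phi = c(1L, 1L, 1L)),
                    list(k = 4, s = 1L, plo = c(1L, 1L, 1L), phi = c(2L, 2L, 2L)))) {
    x <- array(rnorm(6 * 8 * 6 * 2), c(6, 8, 6, 2))
    w <- array(rnorm(case$k^3 * 2 * 3), c(case$k, case$k, case$k, 2, 3))
    b <- rnorm(3)
    fwd <- function(xx, ww)
      strokefeat:::.cpp_conv3d_forward(xx, ww, b, case$s, case$plo, case$phi)
    y <- fwd(x, w)
    dy <- array(rnorm(length(y)), dim(y))
    g <- strokefeat:::.cpp_conv3d_backward(x, w, dy, case$s, case$plo, case$phi)
    eps <- 0.05 # conv is linear in each argument; large eps beats float noise
    for (i in sample(length(w), 5)) {
      wp <- w; wp[i] <- w[i] + eps; wm <- w; wm[i] <- w[i] - eps
      expect_equal(g$dw[i], sum((fwd(x, wp) - fwd(x, wm)) * dy) / (2 * eps),
                   tolerance = 1e-3)
    }
    for (i in sample(length(x), 5)) {
      xp <- x; xp[i] <- x[i] + eps; xm <- x; xm[i] <- x[i] - eps
      expect_equal(g$dx[i], sum((fwd(xp, w) - fwd(xm, w)) * dy) / (2 * eps),
                   tolerance = 1e-3)
    }
    expect_equal(as.numeric(g$db), apply(dy, 4, sum), tolerance = 1e-6)
  }
})

test_that("encoding is deterministic, 100-wide and finite", {
  cfg <- cae_config("mini", input_shape = c(16, 16, 16), seed = 9)
  m1 <- build_cae(cfg)
  m2 <- build_cae(cfg)
  expect_identical(m1$layers, m2$layers)  # seeded init
  x <- array(rnorm(16^3), c(16, 16, 16))
  z1 <- encode(m1, x); z2 <- encode(m1, x)
  expect_identical(z1, z2)
  expect_length(z1, 100)
  expect_named(z1[1], "z000")
  z0 <- encode(m1, array(0, c(16, 16, 16)))
  expect_true(all(is.finite(z0)))
  expect_error(encode(m1, array(0, c(16, 16, 32))), "shape")
})

test_that("a small autoencoder memorizes a single repeated volume", {
  cfg <- cae_config("mini", input_shape = c(16, 16, 16), epochs = 200,
                    seed = 5)
  # blob-with-background target, roughly z-scored scale
  g <- seq(-2, 2, length.out = 16)
  x <- 8 * exp(-outer(outer(g^2, g^2, `+`), g^2, `+`)) +
    array(rnorm(16^3, 0, 0.3), c(16, 16, 16))
  model <- build_cae(cfg)
  model <- train_cae(model, list(x), verbose = FALSE)
  hist <- model$history
  expect_equal(hist$steps[1], 1)  # 2 augmented samples / batch of 2
  expect_lt(hist$train_mse[200], hist$train_mse[1])
  final_mse <- reconstruction_report(model, vol3d(x, 1))$mse
  expect_lt(final_mse, 0.1 * var(as.vector(x)))
})

test_that("reconstruction reports are self-consistent and written to disk", {
  cfg <- cae_config("mini", input_shape = c(16, 16, 16), seed = 2)
  model <- build_cae(cfg)
  x <- vol3d(array(rnorm(16^3), c(16, 16, 16)), 6)
  dir <- tempfile("rec")
  rep <- reconstruction_report(model, x, out_dir = dir, id = "t1")
  expect_equal(rep$mse, mean(rep$difference$data^2))
  expect_equal(rep$difference$data,
               abs(x$data - rep$reconstruction$data))
  expect_true(all(file.exists(file.path(dir, paste0("t1_", c("orig", "recon",
                                                             "diff"), ".nii.gz")))))
  unlink(dir, recursive = TRUE)
})

test_that("z-flip augmentation doubles the samples seen per epoch", {
  cfg <- cae_config("mini", input_shape = c(16, 16, 16), epochs = 1,
                    batch_size = 1, seed = 3)
  vols <- lapply(1:3, function(i) array(rnorm(16^3), c(16, 16, 16)))
  model <- train_cae(build_cae(cfg), vols, verbose = FALSE)
  expect_equal(model$history$steps, 6)  # 3 volumes + 3 flipped copies
})
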