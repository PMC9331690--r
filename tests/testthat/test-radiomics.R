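lev_to_objects <- function(lev, spacing = 1, bin_width = 0.25) {
  # wrap an integer level array as (volume, mask) whose discretization
  # reproduces it exactly
  v <- vol3d(array(ifelse(lev > 0, (lev - 1) * bin_width + bin_width / 2, 0),
                   dim(lev)), spacing)
  m <- lesion_mask(lev > 0, spacing)
  list(v = v, m = m, d = discretize(v, m, bin_width))
}

test_that("discretization follows the min-anchored floor rule", {
  m <- lesion_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)), 1)
  v <- vol3d(array(c(0, 0.24, 0.26, 0.5, 9, 9, 9, 9), c(2, 2, 2)), 1)
  d <- discretize(v, m, 0.25)
  expect_equal(sort(d$gray_levels[m$data == 1]), c(1, 1, 2, 3))
  expect_equal(d$n_levels, 3)
  vc <- vol3d(array(4.2, c(2, 2, 2)), 1)
  dc <- discretize(vc, lesion_mask(array(1, c(2, 2, 2)), 1), 0.25)
  expect_true(all(dc$gray_levels == 1L))
  expect_equal(dc$n_levels, 1)
  expect_error(discretize(v, m, 0), "bin_width")
  expect_error(discretize(v, lesion_mask(array(0, c(2, 2, 2)), 1)), "empty")
})

test_that("GLSZM zones match constructed cases", {
  o <- lev_to_objects(array(rep(c(1L, 0L), c(8, 19)), c(3, 3, 3)))
  P <- build_glszm(o$d)
  expect_equal(attr(P, "N_z"), 1)
  expect_equal(P[1, 8], 1)
  two <- array(0L, c(5, 5, 5)); two[1, 1, 1] <- 1L; two[5, 5, 5] <- 2L
  o2 <- lev_to_objects(two)
  P2 <- build_glszm(o2$d)
  expect_equal(P2[1, 1], 1); expect_equal(P2[2, 1], 1)
  expect_equal(attr(P2, "N_z"), 2)
})

test_that("large-area emphases follow their closed forms", {
  P1 <- matrix(1, 1, 1)
  expect_equal(unname(large_area_emphases(P1, 1)), c(1, 1))
  P2 <- matrix(0, 2, 3); P2[2, 3] <- 1
  la <- large_area_emphases(P2, 1)
  expect_equal(la[["LAHGLE"]], 36)
  expect_equal(la[["LALGLE"]], 9 / 4)
  expect_error(large_area_emphases(P2, 0), "N_z")
  lev <- random_lesion(31)
  o <- lev_to_objects(lev)
  P <- build_glszm(o$d)
  naive <- c(0, 0)
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    naive <- naive + P[i, j] * c(i^2 * j^2, j^2 / i^2)
  expect_equal(unname(large_area_emphases(P, attr(P, "N_z"))),
               naive / attr(P, "N_z"))
})

test_that("mesh volume matches analytic and single-voxel references", {
  m1 <- lesion_mask(array(c(1, rep(0, 124)), c(5, 5, 5)), 3)
  sv <- shape_volumes(m1)
  expect_equal(sv[["voxel_volume_mm3"]], 27)
  expect_equal(sv[["mesh_volume_mm3"]], 13.5)  # half the voxel volume
  # boundary-touching mask must not crash
  mb <- lesion_mask(array(1L, c(3, 3, 3)), 1)
  expect_no_error(shape_volumes(mb))
  r <- 10; g <- 23
  ctr <- (g + 1) / 2
  ball <- array(0L, c(g, g, g))
  idx <- which(ball == 0, arr.ind = TRUE)
  ball[idx[rowSums((idx - ctr)^2) <= r^2, ]] <- 1L
  sv2 <- shape_volumes(lesion_mask(ball, 2))
  analytic <- 4 / 3 * pi * r^3 * 2^3
  expect_lt(abs(sv2[["mesh_volume_mm3"]] - analytic) / analytic, 0.05)
  expect_lte(sv2[["mesh_volume_mm3"]], sv2[["voxel_volume_mm3"]])
})

test_that("texture matrices agree with brute-force enumeration", {
  for (seed in 1:12) {
    lev <- random_lesion(seed)
    o <- lev_to_objects(lev)
    expect_equal(build_glcm(o$d), oracle_glcm(lev), tolerance = 1e-12)
    expect_equal(unname(build_glrlm(o$d)), unname(oracle_glrlm(lev)),
                 tolerance = 1e-12)
    Ps <- build_glszm(o$d)
    attr(Ps, "N_z") <- NULL
    expect_equal(unname(Ps), unname(oracle_glszm(lev)), tolerance = 1e-12)
    Pd <- build_gldm(o$d)
    od <- oracle_gldm(lev)
    expect_equal(unname(Pd), unname(od[, seq_len(ncol(Pd)), drop = FALSE]),
                 tolerance = 1e-12)
    expect_true(all(od[, -seq_len(ncol(Pd))] == 0))
  }
})

test_that("the catalog is exactly the 100-feature registry and always finite", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 100)
  expect_equal(as.integer(table(reg$class)[c("firstorder", "shape", "glcm",
                                             "glrlm", "glszm", "gldm")]),
               c(18, 14, 22, 16, 16, 14))
  tsv <- read.delim(system.file("extdata", "feature_registry.tsv",
                                package = "strokefeat"))
  expect_identical(tsv$name, reg$name)

  spec <- cohort_spec(4, grid = "small", seed = 21)
  sub <- generate_volume(spec, 77)
  f <- extract_features(white_stripe_normalize(sub$volume), sub$mask)
  expect_length(f, 100)
  expect_identical(names(f), reg$name)
  expect_true(all(is.finite(f)))
  # bit-exact reproducibility
  f2 <- extract_features(white_stripe_normalize(sub$volume), sub$mask)
  expect_identical(f, f2)
})

test_that("degenerate lesions produce documented fallbacks", {
  const <- lev_to_objects(array(rep(c(1L, 0L), c(27, 37)), c(4, 4, 4)))
  f <- extract_features(const$v, const$m)
  expect_equal(f[["firstorder_Variance"]], 0)
  expect_equal(f[["firstorder_Uniformity"]], 1)
  expect_equal(f[["glszm_SmallAreaEmphasis"]], 1 / 27^2)
  expect_true(all(is.finite(f)))
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  o1 <- lev_to_objects(single)
  f1 <- extract_features(o1$v, o1$m)
  expect_true(all(is.finite(f1)))
  expect_equal(f1[["shape_MeshVolume"]], 0.5)
})

test_that("intensity shifts move only location features; rotations are neutral", {
  lev <- random_lesion(55, maxdim = 6, nlev = 5)
  o <- lev_to_objects(lev)
  f0 <- extract_features(o$v, o$m)
  vshift <- vol3d(ifelse(o$m$data == 1, o$v$data + 3.25, o$v$data), 1)
  f1 <- extract_features(vshift, o$m)
  loc <- paste0("firstorder_", c("10Percentile", "90Percentile", "Maximum",
                                 "Mean", "Median", "Minimum"))
  texture <- setdiff(names(f0), grep("^(firstorder|shape)", names(f0),
                                     value = TRUE))
  expect_equal(f1[texture], f0[texture], tolerance = 1e-10)
  expect_equal(unname(f1[loc] - f0[loc]), rep(3.25, length(loc)))
  expect_equal(f1[["firstorder_Variance"]], f0[["firstorder_Variance"]])
  # 90-degree rotation about z: permute x/y axes
  rot <- aperm(lev, c(2, 1, 3))[dim(lev)[2]:1, , ]
  orot <- lev_to_objects(rot)
  frot <- extract_features(orot$v, orot$m)
  expect_equal(frot[texture], f0[texture], tolerance = 1e-8)
})

test_that("generator lesions discretize into the designed level band", {
  spec <- cohort_spec(4, grid = "small", seed = 31)
  ngs <- vapply(1:10, function(s) {
    sub <- generate_volume(spec, 600 + s)
    discretize(white_stripe_normalize(sub$volume), sub$mask)$n_levels
  }, 0)
  expect_true(all(ngs >= 4 & ngs <= 64))
})
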