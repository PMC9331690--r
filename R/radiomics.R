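#' The pinned 100-feature radiomics catalog
#'
#' Returns the frozen feature registry: 18 first-order, 14 shape, 22
#' GLCM, 16 GLRLM, 16 GLSZM and 14 GLDM features (exactly 100), in
#' class-then-alphabetical order. The 22-feature GLCM class is the
#' standard 24 minus the two commonly deprecated redundant features
#' (sum average and the maximal correlation coefficient). The order is
#' also stored as a text registry under `inst/extdata/` so CSV columns
#' stay stable across versions.
#'
#' @return A data.frame with columns `class`, `feature`, `name`.
#' @export
feature_registry <- function() {
  cls <- list(
    firstorder = c("10Percentile", "90Percentile", "Energy", "Entropy",
      "InterquartileRange", "Kurtosis", "Maximum", "Mean",
      "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
      "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
      "TotalEnergy", "Uniformity", "Variance"),
    shape = c("Elongation", "Flatness", "LeastAxisLength",
      "MajorAxisLength", "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
      "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
      "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
      "VoxelVolume"),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
      "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
      "JointEnergy", "JointEntropy", "MaximumProbability", "SumEntropy",
      "SumSquares"),
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
    gldm = c("DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis")
  )
  do.call(rbind, lapply(names(cls), function(cn) {
    data.frame(class = cn, feature = cls[[cn]],
               name = paste(cn, cls[[cn]], sep = "_"),
               stringsAsFactors = FALSE)
  }))
}

#' Discretize lesion intensities into gray levels
#'
#' Fixed-bin-width discretization anchored at the within-mask minimum:
#' `level(x) = floor((x - min) / bin_width) + 1`. Levels are consecutive
#' integers from 1; `n_levels` is the maximum level.
#'
#' @param v a [vol3d()] (white-stripe normalized in the pipeline).
#' @param m a [lesion_mask()] on the same grid.
#' @param bin_width positive bin width (default 0.25 on z-scored data).
#' @return A `discretized_lesion`: `gray_levels` (integer array, 0
#'   outside the mask), `n_levels`, `bin_width`, `spacing_mm`, plus the
#'   raw masked intensities.
#' @export
discretize <- function(v, m, bin_width = 0.25) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (!any(m$data == 1L)) stopf("mask is empty")
  if (!all(dim(v$data) == dim(m$data))) stopf("volume/mask grids differ")
  idx <- m$data == 1L
  x <- v$data[idx]
  lev <- array(0L, dim(v$data))
  lev[idx] <- as.integer(floor((x - min(x)) / bin_width) + 1)
  structure(list(gray_levels = lev, n_levels = max(lev), bin_width = bin_width,
                 spacing_mm = m$spacing_mm, values = x),
            class = "discretized_lesion")
}

#' Build texture matrices
#'
#' `build_glcm` returns the symmetric gray-level co-occurrence
#' distribution averaged over the 13 unique 3D directions (each
#' direction's count matrix is normalized before averaging; directions
#' without any voxel pair are skipped). `build_glrlm` returns run-length
#' counts averaged over the same 13 directions. `build_glszm` counts
#' 26-connected constant-level zones, and `build_gldm` counts
#' gray-level dependencies with tolerance 0, where the dependence size
#' `j` is one plus the number of equal-level 26-neighbors.
#'
#' @param d a [discretize()]d lesion.
#' @return A matrix with levels in rows. For `build_glszm` the columns
#'   are zone sizes and attribute `N_z` holds the zone count; for
#'   `build_glcm` the matrix sums to 1 (or is a point mass when the
#'   lesion has no voxel pairs).
#' @export
build_glcm <- function(d) {
  ng <- d$n_levels
  counts <- .cpp_glcm_counts(d$gray_levels, dim(d$gray_levels), ng)
  acc <- matrix(0, ng, ng)
  used <- 0L
  for (k in 1:13) {
    s <- sum(counts[, , k])
    if (s > 0) { acc <- acc + counts[, , k] / s; used <- used + 1L }
  }
  if (used == 0L) { acc <- matrix(0, ng, ng); acc[1, 1] <- 1 }
  else acc <- acc / used
  acc
}

#' @rdname build_glcm
#' @export
build_glrlm <- function(d) {
  ng <- d$n_levels
  counts <- .cpp_glrlm_counts(d$gray_levels, dim(d$gray_levels), ng)
  P <- matrix(0, ng, dim(counts)[2])
  for (k in 1:13) P <- P + counts[, , k]
  P / 13
}

#' @rdname build_glcm
#' @export
build_glszm <- function(d) {
  zones <- .cpp_glszm_zones(d$gray_levels, dim(d$gray_levels))
  ng <- d$n_levels
  P <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  attr(P, "N_z") <- nrow(zones)
  P
}

#' @rdname build_glcm
#' @export
build_gldm <- function(d) {
  P <- .cpp_gldm_counts(d$gray_levels, dim(d$gray_levels), d$n_levels)
  P[, seq_len(max(which(colSums(P) > 0))), drop = FALSE]
}

#' GLSZM large-area emphases
#'
#' `LAHGLE = (1/N_z) * sum_ij P(i,j) i^2 j^2` and
#' `LALGLE = (1/N_z) * sum_ij P(i,j) j^2 / i^2`: zone-size-squared
#' emphases weighted up (down) by the squared gray level. These are the
#' catalog entries most sensitive to large contiguous hyper-/hypo-
#' intense zones inside the lesion.
#'
#' @param P_s a GLSZM count matrix (levels x sizes).
#' @param N_z total zone count (defaults to `sum(P_s)`).
#' @return Named vector `c(LAHGLE, LALGLE)`.
#' @export
large_area_emphases <- function(P_s, N_z = sum(P_s)) {
  if (N_z < 1) stopf("N_z must be >= 1")
  i2 <- (seq_len(nrow(P_s)))^2
  j2 <- (seq_len(ncol(P_s)))^2
  c(LAHGLE = sum(P_s * outer(i2, j2)) / N_z,
    LALGLE = sum(P_s * outer(1 / i2, j2)) / N_z)
}

#' Mesh and voxel volume of a lesion
#'
#' Voxel volume is the voxel count times the voxel volume. Mesh volume
#' is the volume enclosed by the half-voxel iso-surface triangulated by
#' marching tetrahedra (the mask is padded by one zero voxel first, so
#' boundary-touching masks are safe). For a single voxel the mesh
#' encloses exactly half the voxel volume.
#'
#' @param m a [lesion_mask()].
#' @return Named vector `c(mesh_volume_mm3, voxel_volume_mm3)`.
#' @export
shape_volumes <- function(m) {
  if (!any(m$data == 1L)) stopf("mask is empty")
  ms <- mesh_measures(m)
  c(mesh_volume_mm3 = ms[["volume"]],
    voxel_volume_mm3 = sum(m$data) * m$spacing_mm^3)
}

mesh_measures <- function(m) {
  d <- dim(m$data)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m$data
  va <- .cpp_march_tets(padded, dim(padded))
  c(volume = va[1] * m$spacing_mm^3, area = va[2] * m$spacing_mm^2)
}

# ---- feature computations ----------------------------------------------

log2p <- function(p) log2(p[p > 0])

firstorder_features <- function(x, spacing_mm, bin_width) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p1090 <- quantile(x, c(0.10, 0.90), names = FALSE, type = 7)
  core <- x[x >= p1090[1] & x <= p1090[2]]
  lev <- floor((x - min(x)) / bin_width)
  p <- tabulate(lev + 1) / n
  c(`10Percentile` = p1090[1], `90Percentile` = p1090[2],
    Energy = sum(x^2),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    InterquartileRange = diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)),
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Maximum = max(x), Mean = mu,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Median = median(x), Minimum = min(x), Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation =
      if (length(core)) mean(abs(core - mean(core))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    TotalEnergy = spacing_mm^3 * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2)
}

shape_features <- function(m) {
  sp <- m$spacing_mm
  idx <- which(m$data == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  ms <- mesh_measures(m)
  mesh_v <- ms[["volume"]]; area <- ms[["area"]]
  coords <- idx * sp
  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords) * (n - 1) / n, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  bnd <- which(mask_boundary(m$data), arr.ind = TRUE) * sp
  maxdist <- function(pts, cols) {
    if (nrow(pts) < 2) return(0)
    sqrt(max(dist(pts[, cols, drop = FALSE])^2))
  }
  plane_max <- function(fix_col, use_cols) {
    groups <- split.data.frame(bnd, bnd[, fix_col])
    max(vapply(groups, maxdist, 0, cols = use_cols))
  }
  c(Elongation = elong, Flatness = flat,
    LeastAxisLength = axis_len[3], MajorAxisLength = axis_len[1],
    Maximum2DDiameterColumn = plane_max(2, c(1, 3)),
    Maximum2DDiameterRow = plane_max(1, c(2, 3)),
    Maximum2DDiameterSlice = plane_max(3, c(1, 2)),
    Maximum3DDiameter = maxdist(bnd, 1:3),
    MeshVolume = mesh_v, MinorAxisLength = axis_len[2],
    Sphericity = if (area > 0) (36 * pi * mesh_v^2)^(1 / 3) / area else 1,
    SurfaceArea = area,
    SurfaceVolumeRatio = if (mesh_v > 0) area / mesh_v else 0,
    VoxelVolume = n * sp^3)
}

glcm_features <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  lv <- seq_len(ng)
  px <- rowSums(p)
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), 0)
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), 0)
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  da <- sum(kd * pxy_diff)
  hxy <- -sum(log2p(p) * p[p > 0])
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- -sum(log2p(pxpy) * pxpy[pxpy > 0])
  hx <- -sum(log2p(px) * px[px > 0])
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offd <- i != j
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(log2p(pxy_diff) * pxy_diff[pxy_diff > 0]),
    DifferenceVariance = sum((kd - da)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1, Imc2 = imc2,
    InverseVariance = sum(p[offd] / (i[offd] - j[offd])^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = -sum(log2p(pxy_sum) * pxy_sum[pxy_sum > 0]),
    SumSquares = sig2)
}

# Shared size/run/dependence matrix features. P: levels x sizes counts
# (possibly fractional after direction averaging); np: voxel count.
srm_features <- function(P, np) {
  nr <- sum(P)
  i <- row(P); j <- col(P)
  pg <- rowSums(P); ps <- colSums(P)
  pn <- P / nr
  mu_i <- sum(row(pn) * pn); mu_j <- sum(col(pn) * pn)
  list(
    sre = sum(ps / seq_len(ncol(P))^2) / nr,
    lre = sum(ps * seq_len(ncol(P))^2) / nr,
    gln = sum(pg^2) / nr,
    glnn = sum(pg^2) / nr^2,
    glv = sum(pn * (i - mu_i)^2),
    hgle = sum(pg * seq_len(nrow(P))^2) / nr,
    lgle = sum(pg / seq_len(nrow(P))^2) / nr,
    rln = sum(ps^2) / nr,
    rlnn = sum(ps^2) / nr^2,
    rp = nr / np,
    rv = sum(pn * (j - mu_j)^2),
    rent = -sum(log2p(pn) * pn[pn > 0]),
    srhgle = sum(P * outer(seq_len(nrow(P))^2, 1 / seq_len(ncol(P))^2)) / nr,
    srlgle = sum(P * outer(1 / seq_len(nrow(P))^2, 1 / seq_len(ncol(P))^2)) / nr,
    lrhgle = sum(P * outer(seq_len(nrow(P))^2, seq_len(ncol(P))^2)) / nr,
    lrlgle = sum(P * outer(1 / seq_len(nrow(P))^2, seq_len(ncol(P))^2)) / nr)
}

#' Extract the full 100-feature vector for one lesion
#'
#' First-order features are computed on the raw (normalized) intensities
#' within the mask; texture features on the [discretize()]d lesion with
#' GLCM/GLRLM direction-averaged over the 13 unique 3D directions, GLSZM
#' zones and GLDM dependencies 26-connected, and GLDM tolerance 0.
#' Single-voxel masks yield the documented single-zone fallbacks; every
#' value is finite.
#'
#' @param v a normalized [vol3d()].
#' @param m a [lesion_mask()].
#' @param bin_width discretization bin width (default 0.25).
#' @return Named numeric vector of length 100, ordered as
#'   [feature_registry()].
#' @export
extract_features <- function(v, m, bin_width = 0.25) {
  d <- discretize(v, m, bin_width)
  np <- sum(m$data)
  fo <- firstorder_features(d$values, m$spacing_mm, bin_width)
  sh <- shape_features(m)
  gc <- glcm_features(build_glcm(d))
  reg <- feature_registry()
  srm_map <- function(P, keys) {
    f <- srm_features(P, np)
    vapply(keys, function(k) f[[k]], 0)
  }
  rl <- srm_map(build_glrlm(d),
    c(gln = "gln", glnn = "glnn", glv = "glv", hgle = "hgle", lre = "lre",
      lrhgle = "lrhgle", lrlgle = "lrlgle", lgle = "lgle", rent = "rent",
      rln = "rln", rlnn = "rlnn", rp = "rp", rv = "rv", sre = "sre",
      srhgle = "srhgle", srlgle = "srlgle"))
  sz <- srm_map(build_glszm(d),
    c(gln = "gln", glnn = "glnn", glv = "glv", hgle = "hgle", lre = "lre",
      lrhgle = "lrhgle", lrlgle = "lrlgle", lgle = "lgle", rln = "rln",
      rlnn = "rlnn", sre = "sre", srhgle = "srhgle", srlgle = "srlgle",
      rent = "rent", rp = "rp", rv = "rv"))
  dm <- srm_map(build_gldm(d),
    c(rent = "rent", rln = "rln", rlnn = "rlnn", rv = "rv", gln = "gln",
      glv = "glv", hgle = "hgle", lre = "lre", lrhgle = "lrhgle",
      lrlgle = "lrlgle", lgle = "lgle", sre = "sre", srhgle = "srhgle",
      srlgle = "srlgle"))
  out <- c(fo, sh, gc, rl, sz, dm)
  names(out) <- reg$name
  stopifnot(length(out) == 100L, all(is.finite(out)))
  out
}

#' Radiomic feature table for a cohort
#'
#' @param volumes named list of normalized [vol3d()]s.
#' @param masks named list of matching [lesion_mask()]s.
#' @param bin_width discretization bin width.
#' @return data.frame with `id` plus 100 feature columns.
#' @export
extract_feature_table <- function(volumes, masks, bin_width = 0.25) {
  stopifnot(length(volumes) == length(masks))
  rows <- lapply(seq_along(volumes), function(k)
    extract_features(volumes[[k]], masks[[k]], bin_width))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(id = names(volumes) %||% as.character(seq_along(volumes)), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
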