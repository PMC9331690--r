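#' White-stripe intensity normalization
#'
#' Locates the dominant mode of the within-brain intensity histogram by
#' kernel density estimation, takes the "stripe" of voxels whose
#' intensities fall inside the quantile window of half-width
#' `stripe_width` around the mode's CDF position, and z-scores the
#' brain voxels with the stripe mean and standard deviation. The stripe
#' mean maps to 0 and its sd to 1; voxels outside the brain mask are set
#' to 0 so that padding stays background-neutral. Every ingredient
#' (nrd0 bandwidth, empirical CDF, type-7 quantiles) is equivariant
#' under positive affine intensity transforms, so the output is
#' invariant to them, and the procedure is idempotent.
#'
#' For DWI-like images the dominant mode is taken to be normal-appearing
#' tissue; the T1/T2-specific "first/last peak" variants of the original
#' method are not implemented.
#'
#' @param v a [vol3d()].
#' @param brain_mask logical/0-1 array; defaults to nonzero voxels.
#' @param stripe_width quantile half-width of the stripe (default 0.05,
#'   the method's published default).
#' @return A normalized [vol3d()].
#' @export
white_stripe_normalize <- function(v, brain_mask = NULL, stripe_width = 0.05) {
  bm <- if (is.null(brain_mask)) v$data != 0 else brain_mask != 0
  if (!any(bm)) stopf("brain mask is empty")
  x <- v$data[bm]
  if (max(x) - min(x) < .Machine$double.eps * max(abs(x), 1))
    stopf("degenerate (constant) image: no histogram mode")
  # half the nrd0 bandwidth: sharp enough to resolve a tight tissue
  # ridge over a broad background, still affine-equivariant
  dens <- density(x, bw = stats::bw.nrd0(x) / 2, n = 2048)
  mode_mu <- dens$x[which.max(dens$y)]
  pos <- ecdf(x)(mode_mu)
  qs <- quantile(x, c(max(pos - stripe_width, 0), min(pos + stripe_width, 1)),
                 names = FALSE, type = 7)
  stripe <- x[x >= qs[1] & x <= qs[2]]
  if (length(stripe) < 2L || sd(stripe) == 0) stopf("empty or degenerate stripe")
  out <- array(0, dim(v$data))
  out[bm] <- (x - mean(stripe)) / sd(stripe)
  res <- vol3d(out, v$spacing_mm, v$origin_offset)
  attr(res, "white_stripe") <- list(mode = mode_mu, mean = mean(stripe),
                                    sd = sd(stripe), n_stripe = length(stripe))
  res
}

#' Resample a volume to a coarser isotropic spacing
#'
#' Trilinear interpolation onto the coarser grid; the output shape is
#' `ceiling(shape * source / target)`. Upsampling is out of scope and
#' rejected.
#'
#' @param v a [vol3d()].
#' @param target_spacing_mm target isotropic spacing (>= source).
#' @return The resampled [vol3d()].
#' @export
resample_isotropic <- function(v, target_spacing_mm) {
  src <- v$spacing_mm
  if (target_spacing_mm < src) stopf("upsampling (target < source) is not supported")
  if (target_spacing_mm == src) return(v)
  d <- dim(v$data)
  nd <- as.integer(ceiling(d * src / target_spacing_mm))
  # voxel centers at (i - 0.5) * spacing; clamp to the source support
  coords <- lapply(1:3, function(a) {
    ci <- ((seq_len(nd[a]) - 0.5) * target_spacing_mm) / src + 0.5
    pmin(pmax(ci, 1), d[a])
  })
  i0 <- lapply(1:3, function(a) pmin(floor(coords[[a]]), d[a] - 1))
  fr <- lapply(1:3, function(a) coords[[a]] - i0[[a]])
  gx <- rep(seq_len(nd[1]), times = nd[2] * nd[3])
  gy <- rep(rep(seq_len(nd[2]), each = nd[1]), times = nd[3])
  gz <- rep(seq_len(nd[3]), each = nd[1] * nd[2])
  out <- numeric(prod(nd))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (ifelse(cx == 1, fr[[1]][gx], 1 - fr[[1]][gx]) *
          ifelse(cy == 1, fr[[2]][gy], 1 - fr[[2]][gy]) *
          ifelse(cz == 1, fr[[3]][gz], 1 - fr[[3]][gz]))
    idx <- cbind(i0[[1]][gx] + cx, i0[[2]][gy] + cy, i0[[3]][gz] + cz)
    out <- out + w * v$data[idx]
  }
  vol3d(array(out, nd), target_spacing_mm)
}

#' Pad a volume to the autoencoder grid
#'
#' Symmetric zero padding with the extra voxel on the high side when the
#' difference is odd; the low-side pad is recorded in `origin_offset` so
#' [crop_from_cae_grid()] restores the input bit-exactly.
#'
#' @param v a [vol3d()].
#' @param target integer triple, default `c(64, 80, 64)`.
#' @return The padded [vol3d()].
#' @export
pad_to_cae_grid <- function(v, target = c(64L, 80L, 64L)) {
  d <- dim(v$data)
  if (any(d > target))
    stopf("input (%s) larger than the target grid (%s)",
          paste(d, collapse = "x"), paste(target, collapse = "x"))
  lo <- as.integer(floor((target - d) / 2))
  out <- array(0, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    v$data
  vol3d(out, v$spacing_mm, origin_offset = lo)
}

#' @rdname pad_to_cae_grid
#' @param shape original (pre-padding) shape to crop back to.
#' @export
crop_from_cae_grid <- function(v, shape) {
  lo <- v$origin_offset
  d <- as.integer(shape)
  vol3d(v$data[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
               lo[3] + seq_len(d[3]), drop = FALSE],
        v$spacing_mm)
}
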