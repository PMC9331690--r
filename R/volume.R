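#' 3D scalar volume with isotropic spacing
#'
#' Lightweight container used throughout the pipeline. `origin_offset`
#' records low-side padding (in voxels) applied by [pad_to_cae_grid()] so
#' that cropping is exact.
#'
#' @param data numeric 3D array.
#' @param spacing_mm isotropic voxel spacing in millimetres.
#' @param origin_offset integer triple of low-side padding voxels.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, spacing_mm, origin_offset = c(0L, 0L, 0L)) {
  if (length(dim(data)) != 3L) stopf("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stopf("all dimensions must be >= 1")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stopf("`spacing_mm` must be a positive scalar")
  structure(
    list(data = data, spacing_mm = spacing_mm,
         origin_offset = as.integer(origin_offset)),
    class = "vol3d"
  )
}

#' Binary lesion mask on a volume grid
#'
#' @param data array of 0/1 values (logical or numeric).
#' @param spacing_mm isotropic voxel spacing in millimetres.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing_mm) {
  if (length(dim(data)) != 3L) stopf("`data` must be a 3D array")
  d <- array(as.integer(data != 0), dim = dim(data))
  if (!all(d %in% c(0L, 1L))) stopf("mask values must be binary")
  structure(list(data = d, spacing_mm = spacing_mm), class = "lesion_mask")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels @ %g mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"), x$spacing_mm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels @ %g mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"), x$spacing_mm,
              sum(x$data)))
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' Spacing is taken from (written to) the NIfTI pixdim; only isotropic
#' grids are supported.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param v,m a [vol3d()] or [lesion_mask()].
#' @return `read_volume` returns a `vol3d`; `read_mask` a `lesion_mask`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (max(abs(sp - sp[1])) > 1e-6) stopf("non-isotropic NIfTI not supported")
  vol3d(array(as.numeric(img), dim = dim(img)), spacing_mm = sp[1])
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- rep(v$spacing_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  lesion_mask(v$data > 0.5, v$spacing_mm)
}

#' @rdname read_volume
#' @export
write_mask <- function(m, path) {
  write_volume(vol3d(array(as.numeric(m$data), dim(m$data)), m$spacing_mm), path)
}

# Separable Gaussian blur with edge-renormalized truncated kernels.
gaussian_blur3d <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  blur_axis <- function(a, axis) {
    n <- dim(a)[axis]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-0.5 * ((i - j) / sigma_vox)^2))
    K[abs(row(K) - col(K)) > ceiling(4 * sigma_vox)] <- 0
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- K %*% matrix(ap, nrow = n)
    aperm(array(m, d), order(perm))
  }
  for (ax in 1:3) a <- blur_axis(a, ax)
  a
}

# Boundary voxels of a binary array (any 6-neighbor outside the mask or
# the array edge).
mask_boundary <- function(d) {
  dd <- dim(d)
  padded <- array(0L, dd + 2L)
  padded[2:(dd[1] + 1), 2:(dd[2] + 1), 2:(dd[3] + 1)] <- d
  cnt <- array(0L, dd)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    off <- shifts[s, ]
    cnt <- cnt + padded[(2:(dd[1] + 1)) + off[1],
                        (2:(dd[2] + 1)) + off[2],
                        (2:(dd[3] + 1)) + off[3]]
  }
  d == 1L & cnt < 6L
}
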