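#' Threshold-based lesion segmentation
#'
#' A deliberately simple intensity segmenter for white-stripe normalized
#' volumes: voxels at or above `z_threshold` inside the brain mask are
#' kept, 26-connected components smaller than `min_volume_ml` are
#' dropped, and internal holes are filled so that hypointense
#' (hemorrhage-like) cores remain part of the lesion. When nothing
#' survives, an empty mask is returned with a warning rather than an
#' error.
#'
#' @param v a white-stripe normalized [vol3d()].
#' @param z_threshold z-score threshold (default 2.5).
#' @param min_volume_ml minimum component volume in ml (default 0.5).
#' @param brain_mask logical/0-1 array; defaults to nonzero voxels.
#' @return A [lesion_mask()]; attribute `empty` is `TRUE` when no voxel
#'   survived.
#' @export
segment_threshold <- function(v, z_threshold = 2.5, min_volume_ml = 0.5,
                              brain_mask = NULL) {
  bm <- if (is.null(brain_mask)) v$data != 0 else brain_mask != 0
  th <- array(as.integer(v$data >= z_threshold & bm), dim(v$data))
  min_vox <- min_volume_ml * 1000 / v$spacing_mm^3
  if (any(th == 1L)) {
    lab <- .cpp_cc_label(th, dim(th), 26L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_vox)
    th <- array(as.integer(lab %in% keep & lab > 0L), dim(th))
  }
  if (!any(th == 1L)) {
    warning("no voxel survived thresholding; returning an empty mask",
            call. = FALSE)
    m <- lesion_mask(th, v$spacing_mm)
    attr(m, "empty") <- TRUE
    return(m)
  }
  m <- lesion_mask(fill_holes(th), v$spacing_mm)
  attr(m, "empty") <- FALSE
  m
}

# Fill cavities: background voxels (6-connectivity) not connected to the
# array border become lesion.
fill_holes <- function(mask) {
  bg <- array(as.integer(mask == 0L), dim(mask))
  lab <- .cpp_cc_label(bg, dim(bg), 6L)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  array(as.integer(mask == 1L | !(lab %in% c(0L, border))), d)
}

#' Lesion volume in millilitres
#'
#' Voxel count times the voxel volume: the follow-up infarct volume
#' (FIV) feature.
#'
#' @param m a [lesion_mask()].
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(m) {
  sum(m$data) * m$spacing_mm^3 / 1000
}
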