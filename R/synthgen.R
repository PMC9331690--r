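#' Specify a synthetic DWI cohort
#'
#' The generator emulates follow-up diffusion-weighted imaging at the
#' working resolution of the analysis: an ellipsoidal brain with a
#' dominant white-matter-like intensity mode, a secondary darker tissue
#' class, and one connected hyperintense lesion per subject. Two planted
#' parameters drive the outcome label: the lesion volume `V` (ml) and a
#' within-lesion intensity heterogeneity `h` in `[0, 1]`. At `h = 0` the
#' lesion is near-uniform; as `h` grows it splits into contiguous low-
#' and high-intensity zones (the structure that GLSZM large-area
#' features measure). The favorable-outcome probability follows a
#' logistic model in which heterogeneity carries three times the weight
#' of log-volume, so texture dominates the planted signal.
#'
#' Frozen defaults: `h` is drawn from a Beta(0.3, 0.3) rescaled to
#' `heterogeneity_range` (bimodal: most lesions are either homogeneous
#' or strongly heterogeneous, as with hemorrhage-like cores), and the
#' volume is log-uniform on `lesion_volume_range_ml`. `beta0 = 5.2`
#' balances the favorable rate near 50%.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid `"mni3mm"` (61 x 73 x 61 at 3 mm), `"small"`
#'   (31 x 37 x 31 at 6 mm), or an integer triple.
#' @param spacing_mm voxel spacing; filled in by the presets.
#' @param lesion_volume_range_ml interval the target lesion volume is
#'   drawn from (log-uniform), in ml.
#' @param heterogeneity_range interval within `[0, 1]` for `h`.
#' @param beta0,beta_h,beta_v logistic coefficients of the outcome
#'   model; see [generate_outcome()].
#' @param label_noise_sd sd of the Gaussian noise added to the linear
#'   predictor.
#' @param test_fraction,val_fraction split fractions used by
#'   [generate_cohort()].
#' @param seed cohort seed; identical spec + seed give a bit-identical
#'   cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 206, grid = "mni3mm", spacing_mm = NULL,
                        lesion_volume_range_ml = c(5, 150),
                        heterogeneity_range = c(0, 1),
                        beta0 = 5.2, beta_h = 3, beta_v = 1,
                        label_noise_sd = 0.5,
                        test_fraction = 0.2, val_fraction = 0,
                        seed = 1) {
  if (is.character(grid)) {
    preset <- switch(grid,
      mni3mm = list(shape = c(61L, 73L, 61L), spacing = 3),
      small  = list(shape = c(31L, 37L, 31L), spacing = 6),
      stopf("unknown grid preset '%s'", grid))
    grid_shape <- preset$shape
    spacing_mm <- spacing_mm %||% preset$spacing
  } else {
    grid_shape <- as.integer(grid)
    spacing_mm <- spacing_mm %||% 3
  }
  spec <- list(n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
               spacing_mm = spacing_mm,
               lesion_volume_range_ml = lesion_volume_range_ml,
               heterogeneity_range = heterogeneity_range,
               beta0 = beta0, beta_h = beta_h, beta_v = beta_v,
               label_noise_sd = label_noise_sd,
               test_fraction = test_fraction, val_fraction = val_fraction,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 2L) stopf("n_subjects must be >= 2")
  if (spec$spacing_mm <= 0) stopf("spacing_mm must be > 0")
  hr <- spec$heterogeneity_range
  if (length(hr) != 2 || hr[1] < 0 || hr[2] > 1 || hr[1] > hr[2])
    stopf("heterogeneity_range must be an interval within [0, 1]")
  vr <- spec$lesion_volume_range_ml
  if (length(vr) != 2 || vr[1] <= 0 || vr[1] > vr[2])
    stopf("lesion_volume_range_ml must be a positive interval")
  if (spec$label_noise_sd < 0) stopf("label_noise_sd must be >= 0")
  invisible(spec)
}

# Raw-intensity constants of the synthetic tissue model (arbitrary
# scanner units; white-stripe normalization removes the scale). The
# normal-appearing white-matter class is a tight compactly-supported
# ridge at 100 +/- 1 holding ~15% of the brain mass over a broad darker
# background: the +/-5% quantile stripe covers two thirds of the WM
# class, so the stripe sd is commensurate with the WM spread and the
# bounded support keeps the entire WM class below z ~ 2.6, which is
# what makes the z >= 2.5 segmentation threshold clean.
SYNTH <- list(
  gm_lo = 50, gm_hi = 95, wm = 100, wm_halfwidth = 1.0, wm_frac = 0.15,
  class_smooth_mm = 9,
  lesion_base = 105, lesion_delta = 1.2, lesion_noise_sd = 0.45,
  zone_smooth_mm = 12, shape_smooth_mm = 6, shape_radial_weight = 1.2,
  brain_axes_frac = 0.35, center_frac = 0.55
)

brain_ellipsoid <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  ax <- SYNTH$brain_axes_frac * grid_shape
  ix <- ((seq_len(grid_shape[1]) - ctr[1]) / ax[1])^2
  iy <- ((seq_len(grid_shape[2]) - ctr[2]) / ax[2])^2
  iz <- ((seq_len(grid_shape[3]) - ctr[3]) / ax[3])^2
  r2 <- outer(outer(ix, iy, `+`), iz, `+`)
  r2 <= 1
}

#' Generate one synthetic subject
#'
#' Pure function of `(spec, subject_seed)`: the same pair always yields
#' bit-identical voxel data. The lesion is painted as an exact-count
#' best-first region grown over a smoothed random score field, so the
#' painted voxel volume matches the requested volume to within half a
#' voxel.
#'
#' @param spec a [cohort_spec()].
#' @param subject_seed integer seed for this subject.
#' @param id subject identifier string.
#' @param h,v_ml optionally pin the planted heterogeneity / volume
#'   instead of drawing them from the spec.
#' @return A `subject` list with fields `id`, `volume` ([vol3d()]),
#'   `mask` ([lesion_mask()]), `outcome` (0/1), `h_true`, `v_true_ml`.
#' @export
generate_volume <- function(spec, subject_seed, id = sprintf("s%06d", subject_seed),
                            h = NULL, v_ml = NULL) {
  validate_cohort_spec(spec)
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  with_seed(subject_seed, {
    hr <- spec$heterogeneity_range
    h <- h %||% (hr[1] + (hr[2] - hr[1]) * rbeta(1, 0.3, 0.3))
    vr <- spec$lesion_volume_range_ml
    v_ml <- v_ml %||% exp(runif(1, log(vr[1]), log(vr[2])))
    if (h < 0 || h > 1) stopf("h must lie in [0, 1]")
    if (v_ml <= 0) stopf("v_ml must be positive")

    brain <- brain_ellipsoid(gs)
    n_target <- max(1L, round(v_ml * 1000 / sp^3))
    if (n_target > 0.5 * sum(brain))
      stopf("grid too small to contain a %.1f ml lesion at %g mm spacing",
            v_ml, sp)

    # background tissue: broad darker class + tight dominant WM-like mode
    g1 <- gaussian_blur3d(array(rnorm(prod(gs)), gs), SYNTH$class_smooth_mm / sp)
    g2 <- gaussian_blur3d(array(rnorm(prod(gs)), gs), SYNTH$class_smooth_mm / sp)
    tissue <- SYNTH$gm_lo + (SYNTH$gm_hi - SYNTH$gm_lo) *
      pnorm((g1 - mean(g1)) / sd(g1))
    wm_region <- g2 >= quantile(g2[brain], 1 - SYNTH$wm_frac)
    tissue[wm_region] <- runif(sum(wm_region), SYNTH$wm - SYNTH$wm_halfwidth,
                               SYNTH$wm + SYNTH$wm_halfwidth)

    # lesion support: exact-count blobby region inside the brain
    ctr <- (gs + 1) / 2
    ax <- SYNTH$brain_axes_frac * gs * SYNTH$center_frac
    center <- round(ctr + ax * runif(3, -1, 1))
    shape_field <- gaussian_blur3d(array(rnorm(prod(gs)), gs),
                                   SYNTH$shape_smooth_mm / sp)
    r_t <- (3 * n_target / (4 * pi))^(1 / 3)
    ix <- (seq_len(gs[1]) - center[1])^2
    iy <- (seq_len(gs[2]) - center[2])^2
    iz <- (seq_len(gs[3]) - center[3])^2
    d2 <- outer(outer(ix, iy, `+`), iz, `+`)
    score <- shape_field / sd(shape_field) -
      SYNTH$shape_radial_weight * d2 / r_t^2
    score[!brain] <- -Inf
    start0 <- (center[1] - 1) + gs[1] * ((center[2] - 1) + gs[2] * (center[3] - 1))
    les <- .cpp_region_grow(as.numeric(score), gs, as.integer(start0),
                            as.integer(n_target))
    if (length(les) == 0L)
      stopf("grid too small to contain a %.1f ml lesion at %g mm spacing", v_ml, sp)
    les <- array(les, gs)

    # lesion intensities: hyperintense base + h-scaled contiguous zones
    zone <- gaussian_blur3d(array(rnorm(prod(gs)), gs), SYNTH$zone_smooth_mm / sp)
    zsign <- ifelse(zone >= median(zone[les == 1L]), 1, -1)
    vox <- tissue
    vox[les == 1L] <- SYNTH$lesion_base +
      h * SYNTH$lesion_delta * zsign[les == 1L] +
      rnorm(sum(les), 0, SYNTH$lesion_noise_sd)
    vox[!brain] <- 0

    outcome <- generate_outcome(h, v_ml, spec)
    structure(list(id = id, volume = vol3d(vox, sp),
                   mask = lesion_mask(les, sp),
                   outcome = outcome, h_true = h, v_true_ml = v_ml),
              class = "subject")
  })
}

#' Draw a binary outcome from the planted logistic model
#'
#' `P(favorable) = plogis(beta0 - beta_h * h - beta_v * log(v_ml) + eps)`
#' with `eps ~ N(0, label_noise_sd)`. With the default coefficients
#' (`beta_h = 3`, `beta_v = 1`) heterogeneity outweighs log-volume.
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param h heterogeneity in `[0, 1]`.
#' @param v_ml lesion volume in ml (> 0).
#' @param spec a [cohort_spec()] carrying the coefficients.
#' @return 0 or 1 (1 = favorable outcome, the mRS 0-2 analogue).
#' @export
generate_outcome <- function(h, v_ml, spec) {
  if (any(h < 0 | h > 1)) stopf("h must lie in [0, 1]")
  if (any(v_ml <= 0)) stopf("v_ml must be positive")
  eta <- spec$beta0 - spec$beta_h * h - spec$beta_v * log(v_ml) +
    rnorm(length(h), 0, spec$label_noise_sd)
  rbinom(length(h), 1L, plogis(eta))
}

#' Split subject ids into train / validation / test sets
#'
#' `|test| = floor(test_fraction * n)`, `|val| = floor(val_fraction * n)`,
#' and training receives the remainder, so 206 subjects at a 0.2 test
#' fraction give 41 test scans and 316 give a 253-subject training set.
#' When labels are supplied the partition is stratified by outcome with
#' largest-remainder rounding inside each stratum.
#'
#' @param ids character or integer vector of subject ids.
#' @param test_fraction fraction in (0, 1).
#' @param val_fraction fraction in `[0, 1)`; `test + val < 1`.
#' @param seed RNG seed for the shuffle.
#' @param labels optional binary outcome vector aligned with `ids`.
#' @return A list with components `train`, `val`, `test`.
#' @export
split_cohort <- function(ids, test_fraction = 0.2, val_fraction = 0,
                         seed = 1, labels = NULL) {
  n <- length(ids)
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must lie in (0, 1)")
  if (val_fraction < 0 || test_fraction + val_fraction >= 1)
    stopf("fractions must satisfy test + val < 1")
  n_test <- floor(test_fraction * n)
  n_val <- floor(val_fraction * n)
  if (n_test < 1 || n - n_test - n_val < 1)
    stopf("split would produce an empty partition")

  groups <- if (is.null(labels)) rep(1L, n) else as.integer(labels)
  with_seed(seed, {
    ord <- sample.int(n)
    assn <- rep("train", n)
    take <- function(pool_by_group, total) {
      sizes <- vapply(pool_by_group, length, 1L)
      if (total == 0 || sum(sizes) == 0) return(character(0))
      quota <- sizes / sum(sizes) * total
      base <- floor(quota)
      rem <- total - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      unlist(lapply(seq_along(pool_by_group),
                    function(g) head(pool_by_group[[g]], base[g])))
    }
    pool <- split(ord, groups[ord])
    test_idx <- take(pool, n_test)
    pool <- lapply(pool, setdiff, test_idx)
    val_idx <- take(pool, n_val)
    assn[as.integer(test_idx)] <- "test"
    assn[as.integer(val_idx)] <- "val"
    list(train = ids[assn == "train"], val = ids[assn == "val"],
         test = ids[assn == "test"])
  })
}

#' Split by explicit counts
#'
#' Mirrors the study recipe of fixing 144 training, 21 validation and 41
#' test scans by count rather than by fraction.
#'
#' @inheritParams split_cohort
#' @param n_train,n_val,n_test explicit partition sizes summing to
#'   `length(ids)`.
#' @return A list with components `train`, `val`, `test`.
#' @export
split_counts <- function(ids, n_train, n_val, n_test, seed = 1) {
  if (n_train + n_val + n_test != length(ids))
    stopf("counts must sum to the number of ids")
  if (min(n_train, n_test) < 1) stopf("train and test must be nonempty")
  with_seed(seed, {
    ord <- sample(ids)
    list(train = ord[seq_len(n_train)],
         val = ord[n_train + seq_len(n_val)],
         test = ord[n_train + n_val + seq_len(n_test)])
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort` list: `subjects` (list of subjects), `table`
#'   (data.frame with `id`, `outcome`, `h_true`, `v_true_ml`, `split`),
#'   and the `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    generate_volume(spec, derive_seed(spec$seed, i), id = sprintf("s%04d", i))
  })
  tab <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    outcome = vapply(subjects, `[[`, 0L, "outcome"),
    h_true = vapply(subjects, `[[`, 0, "h_true"),
    v_true_ml = vapply(subjects, `[[`, 0, "v_true_ml"),
    stringsAsFactors = FALSE
  )
  sp <- split_cohort(tab$id, spec$test_fraction, spec$val_fraction,
                     seed = derive_seed(spec$seed, 0), labels = tab$outcome)
  tab$split <- "train"
  tab$split[tab$id %in% sp$val] <- "val"
  tab$split[tab$id %in% sp$test] <- "test"
  structure(list(subjects = subjects, table = tab, spec = spec),
            class = "cohort")
}

#' Write a cohort to disk as NIfTI pairs plus a cohort CSV
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_volume(s$volume, file.path(dir, paste0(s$id, "_dwi.nii.gz")))
    write_mask(s$mask, file.path(dir, paste0(s$id, "_mask.nii.gz")))
  }
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
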