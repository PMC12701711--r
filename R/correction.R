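#' Mean lung intensity surrounding an artifact
#'
#' Computes the fill value for the localized correction: the mean intensity
#' over lung-mask voxels inside a morphological shell around the artifact
#' (dilation of the artifact by `shell` voxels minus the artifact itself).
#' Falls back to the global lung mean (excluding artifact voxels where
#' possible) when the shell contains no lung voxels.
#'
#' @param v normalized [ct_volume()].
#' @param lung the paired [lung_mask()] (nonempty).
#' @param art an [artifact_mask()]; label 1 defines the artifact.
#' @param shell shell radius in voxels (default 5).
#' @return scalar fill value in \[0, 1\].
#' @export
surrounding_lung_mean <- function(v, lung, art, shell = 5) {
  x <- vol_data(v)
  lg <- vol_data(lung) > 0
  a <- vol_data(art) == 1L
  stopifnot_same_shape(x, lg); stopifnot_same_shape(x, a)
  if (!any(lg)) stop("lung mask has no voxels")
  ring <- dilate_ball(a, shell) & !a & lg
  if (any(ring)) return(mean(x[ring]))
  rest <- lg & !a
  if (any(rest)) {
    warning("artifact shell contains no lung voxels; using the global lung mean")
    return(mean(x[rest]))
  }
  warning("artifact covers all lung voxels; using the mean over the (artifact) lung")
  mean(x[lg])
}

#' Apply the localized artifact correction
#'
#' Camouflages phase-binning artifact voxels (label 1) by replacing their
#' intensities with the fill value; interpolation-artifact voxels (label 2)
#' and background are untouched. This does not restore the underlying
#' anatomy - it removes the duplicated/cut-off structures that derail
#' intensity-based lung segmentation.
#'
#' @param v normalized [ct_volume()].
#' @param art an [artifact_mask()].
#' @param fill_value intensity used for replacement (see
#'   [surrounding_lung_mean()]).
#' @param pad bounding-box padding recorded for downstream evaluation.
#' @return list with `corrected` (volume), `fill_value`, `n_replaced` and
#'   `bbox` (the padded artifact bounding box, NULL when no label-1 voxels).
#' @export
apply_correction <- function(v, art, fill_value, pad = 3) {
  x <- vol_data(v)
  a <- vol_data(art) == 1L
  stopifnot_same_shape(x, a)
  if (fill_value < 0 || fill_value > 1) stop("fill value must lie in [0, 1]")
  n <- sum(a)
  bb <- NULL
  if (n > 0) {
    x[a] <- fill_value
    bb <- expand_bbox(bbox_of(a), pad, dim(x))
  }
  corrected <- if (inherits(v, "ct_volume"))
    ct_volume(x, v$spacing, v$phase, v$domain) else x
  list(corrected = corrected, fill_value = fill_value, n_replaced = n,
       bbox = bb)
}

#' Threshold-based lung segmentation
#'
#' Simple intensity-based segmenter used to evaluate the correction method
#' on phantom data: thresholds the normalized volume, removes air connected
#' to the volume border (the exterior), and keeps connected components of at
#' least `min_component` voxels.
#'
#' @param v normalized [ct_volume()] or array.
#' @param cut upper intensity bound for lung tissue on the normalized scale
#'   (default 0.35, about -456 HU).
#' @param min_component smallest retained component (voxels).
#' @return logical 3D array of lung voxels.
#' @export
segment_lungs_threshold <- function(v, cut = 0.35, min_component = 100) {
  x <- vol_data(v)
  low <- x < cut
  lab <- label_components(low, 6)
  n <- attr(lab, "n")
  if (n == 0) return(low)
  d <- dim(x)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- setdiff(which(sizes >= min_component), border)
  array(lab %in% keep, d)
}

#' Evaluate the correction on one case
#'
#' Within the padded artifact bounding box, computes Dice of the
#' artifact-affected and corrected lung masks against the clean mask, and
#' the boundary smoothness of all three masks.
#'
#' @param clean_mask,affected_mask,corrected_mask co-registered binary lung
#'   masks (arrays or [lung_mask()]s).
#' @param art the [artifact_mask()] (nonempty label 1).
#' @param pad bounding-box padding in voxels (default 3).
#' @param spacing mm per voxel.
#' @return one-row data.frame with `dice_affected`, `dice_corrected`,
#'   `beta_clean`, `beta_affected`, `beta_corrected`.
#' @export
evaluate_correction <- function(clean_mask, affected_mask, corrected_mask,
                                art, pad = 3, spacing = c(1, 1, 1)) {
  cl <- vol_data(clean_mask) != 0
  af <- vol_data(affected_mask) != 0
  co <- vol_data(corrected_mask) != 0
  a <- vol_data(art) == 1L
  if (!any(a)) stop("artifact mask has no phase-binning voxels")
  bb <- expand_bbox(bbox_of(a), pad, dim(cl))
  clb <- crop_bbox(cl, bb); afb <- crop_bbox(af, bb); cob <- crop_bbox(co, bb)
  beta_of <- function(m) tryCatch(
    boundary_smoothness(m, spacing)$beta, error = function(e) NA_real_)
  data.frame(dice_affected = dice_binary(afb, clb),
             dice_corrected = dice_binary(cob, clb),
             beta_clean = beta_of(clb),
             beta_affected = beta_of(afb),
             beta_corrected = beta_of(cob))
}

#' Phantom study of the localized correction method
#'
#' Generates `n_cases` phantom cases with phase-binning artifacts, corrects
#' the artifact voxels that fall inside the lung region (the voxels that
#' corrupt the lung mask; `region_dilation` widens the region), re-segments
#' the affected and corrected images by intensity thresholding, and
#' evaluates each case within the padded artifact bounding box.
#'
#' @param n_cases number of artifact cases to evaluate.
#' @param grid_shape phantom grid (default `c(40, 40, 40)`).
#' @param seed RNG seed (each case derives its own stream).
#' @param region_dilation dilation (voxels) of the lung mask defining where
#'   artifact voxels are corrected (default 0: the lung itself).
#' @param min_artifact smallest in-region artifact (voxels) for a case to
#'   count.
#' @return data.frame of per-case [evaluate_correction()] rows, with the
#'   cohort statistics of [correction_cohort_stats()] as attribute `stats`.
#' @export
run_correction_study <- function(n_cases = 50, grid_shape = c(40, 40, 40),
                                 seed = 1L, region_dilation = 0,
                                 min_artifact = 50) {
  recs <- list()
  i <- 0L; draw <- 0L
  while (i < n_cases && draw < 4L * n_cases) {
    draw <- draw + 1L
    spec <- phantom_spec(grid_shape = grid_shape,
                         seed = derive_seed(seed, "corr_phantom", draw))
    s <- generate_phase_series(spec)
    v00 <- truncate_and_normalize(s$phases$T00$volume)
    v50 <- truncate_and_normalize(s$phases$T50$volume)
    lung <- s$phases$T00$mask
    res <- infuse_phase_binning(
      v00, v50, lung,
      pb_params(h = 4 + 2 * (draw %% 3), n_stacks = 1,
                sigma_g = 0.8 + 0.2 * (draw %% 4),
                seed = derive_seed(seed, "corr_pb", draw)))
    if (!res$accepted) next
    region <- if (region_dilation > 0) make_region_mask(lung, region_dilation)
    else lung$data > 0
    mm <- array(ifelse(res$mask$data == 1L & region, 1L, 0L), dim(res$mask$data))
    if (sum(mm) < min_artifact) next
    mm <- artifact_mask(mm)
    vi <- surrounding_lung_mean(res$volume, lung, mm)
    cr <- apply_correction(res$volume, mm, vi)
    ev <- evaluate_correction(lung$data > 0,
                              segment_lungs_threshold(res$volume),
                              segment_lungs_threshold(cr$corrected),
                              mm, spacing = spec$spacing)
    i <- i + 1L
    recs[[i]] <- ev
  }
  out <- do.call(rbind, recs)
  attr(out, "stats") <- correction_cohort_stats(out)
  out
}

#' Cohort-level statistics for the correction method
#'
#' Paired Wilcoxon signed-rank test of corrected vs affected Dice, and the
#' Spearman correlation between the clean and corrected boundary smoothness.
#'
#' @param records data.frame of per-case [evaluate_correction()] rows.
#' @return list with medians, `wilcoxon_p` (two-sided) and
#'   `spearman_beta` (list `rho`, `p`).
#' @export
correction_cohort_stats <- function(records) {
  w <- suppressWarnings(
    stats::wilcox.test(records$dice_corrected, records$dice_affected,
                       paired = TRUE))
  ok <- stats::complete.cases(records$beta_clean, records$beta_corrected)
  sp <- paired_spearman(records$beta_clean[ok], records$beta_corrected[ok])
  list(median_dice_affected = stats::median(records$dice_affected),
       median_dice_corrected = stats::median(records$dice_corrected),
       wilcoxon_p = w$p.value, spearman_beta = sp, n = nrow(records))
}
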