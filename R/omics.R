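#' Extract artifact-omics shape features per connected component
#'
#' Treats each sufficiently large connected artifact component as a
#' measurable phenotype and extracts the morphological feature set: voxel
#' volume, bounding-box volume, solidity (volume / convex-hull volume),
#' extent (volume / bounding-box volume), equivalent diameter of the
#' volume-matched sphere, PCA-derived major/intermediate/minor axis lengths
#' (axis length = 4 * sqrt(eigenvalue of the voxel-coordinate covariance),
#' the ellipsoid-axis convention), the three pairwise elongation ratios,
#' flatness (minor / major), and mesh-based sphericity
#' `pi^(1/3) (6V)^(2/3) / A` and compactness `V / A^(3/2)` with `A` the
#' component's isosurface area. All lengths are in voxel units.
#'
#' @param art an [artifact_mask()] (or binary/label array).
#' @param label which artifact label to extract (default 1, phase-binning).
#' @param min_volume smallest component (voxels) to report (default 64).
#' @param connectivity component connectivity (default 26).
#' @return data.frame with one row per retained component and columns
#'   `component`, `volume`, `bbox_volume`, `solidity`, `extent`,
#'   `equivalent_diameter`, `major_axis_length`, `intermediate_axis_length`,
#'   `minor_axis_length`, `elongation_major_minor`,
#'   `elongation_major_intermediate`, `elongation_intermediate_minor`,
#'   `flatness`, `sphericity`, `compactness`.
#' @export
extract_artifact_features <- function(art, label = 1, min_volume = 64,
                                      connectivity = 26) {
  b <- vol_data(art) == label
  if (!any(b)) stop(sprintf("mask has no voxels with label %s", label))
  lab <- label_components(b, connectivity)
  n <- attr(lab, "n")
  rows <- list()
  for (i in seq_len(n)) {
    comp <- lab == i
    V <- sum(comp)
    if (V < max(min_volume, 4)) next
    pts <- which(comp, arr.ind = TRUE)
    bb <- bbox_of(comp)
    bboxV <- prod(bb$hi - bb$lo + 1)
    hullV <- sum(convex_image(comp))
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    axes <- 4 * sqrt(pmax(ev, 0))
    if (axes[3] < 1e-9) next  # PCA degenerate (flat in a direction)
    A <- tryCatch(
      boundary_smoothness(comp, bbox = expand_bbox(bb, 2, dim(comp)))$surface_area,
      error = function(e) NA_real_)
    if (is.na(A) || A <= 0) next  # too thin to mesh at level 0.5
    rows[[length(rows) + 1L]] <- data.frame(
      component = i, volume = V, bbox_volume = bboxV,
      solidity = V / hullV, extent = V / bboxV,
      equivalent_diameter = (6 * V / pi)^(1 / 3),
      major_axis_length = axes[1], intermediate_axis_length = axes[2],
      minor_axis_length = axes[3],
      elongation_major_minor = axes[1] / axes[3],
      elongation_major_intermediate = axes[1] / axes[2],
      elongation_intermediate_minor = axes[2] / axes[3],
      flatness = axes[3] / axes[1],
      sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
      compactness = V / A^(3 / 2))
  }
  if (length(rows) == 0)
    return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

OMICS_FEATURES <- c("volume", "bbox_volume", "solidity", "extent",
                    "equivalent_diameter", "major_axis_length",
                    "intermediate_axis_length", "minor_axis_length",
                    "elongation_major_minor", "elongation_major_intermediate",
                    "elongation_intermediate_minor", "flatness",
                    "sphericity", "compactness")

#' Statistical comparison of two artifact-omics feature tables
#'
#' For each feature: z-scores the pooled sample, tests for difference with a
#' two-sided Mann-Whitney U test, and tests for practical equivalence with
#' TOST (two one-sided Welch t-tests at bounds of +-`eq_bound` standard
#' deviations). Benjamini-Hochberg FDR correction is applied across
#' features, separately to the U p-values and to the TOST p-values. Two
#' distributions are called `equivalent` when both TOST p-values fall below
#' `alpha` (after FDR) and the U test does not flag a difference;
#' `different` when only the U test fires; `both` when the groups are
#' statistically different yet practically equivalent; `inconclusive`
#' otherwise.
#'
#' @param group_a,group_b data.frames of features (as from
#'   [extract_artifact_features()]), >= 3 rows each.
#' @param eq_bound TOST equivalence bound in pooled-SD units (default 0.2).
#' @param alpha significance level (default 0.05).
#' @param features which feature columns to compare (default: those present
#'   in both tables among the canonical set).
#' @return data.frame with one row per feature: `feature`, `u_p`,
#'   `tost_p_lower`, `tost_p_upper`, `tost_p`, `u_q`, `tost_q`, `verdict`.
#' @export
compare_feature_groups <- function(group_a, group_b, eq_bound = 0.2,
                                   alpha = 0.05, features = NULL) {
  if (is.null(features))
    features <- intersect(OMICS_FEATURES,
                          intersect(names(group_a), names(group_b)))
  if (nrow(group_a) < 3 || nrow(group_b) < 3)
    stop("each group needs at least 3 observations")
  rows <- list()
  for (f in features) {
    a <- group_a[[f]]; b <- group_b[[f]]
    pooled <- c(a, b)
    if (stats::sd(pooled) < 1e-12) {
      warning(sprintf("feature '%s' is constant; comparison skipped", f))
      next
    }
    za <- (a - mean(pooled)) / stats::sd(pooled)
    zb <- (b - mean(pooled)) / stats::sd(pooled)
    u_p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    p_lo <- tryCatch(stats::t.test(za, zb, mu = -eq_bound,
                                   alternative = "greater")$p.value,
                     error = function(e) NA_real_)
    p_hi <- tryCatch(stats::t.test(za, zb, mu = eq_bound,
                                   alternative = "less")$p.value,
                     error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, u_p = u_p, tost_p_lower = p_lo, tost_p_upper = p_hi,
      tost_p = max(p_lo, p_hi))
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  out$u_q <- stats::p.adjust(out$u_p, method = "BH")
  out$tost_q <- stats::p.adjust(out$tost_p, method = "BH")
  different <- !is.na(out$u_q) & out$u_q < alpha
  equivalent <- !is.na(out$tost_q) & out$tost_q < alpha
  out$verdict <- ifelse(different & equivalent, "both",
                        ifelse(equivalent, "equivalent",
                               ifelse(different, "different", "inconclusive")))
  rownames(out) <- NULL
  out
}

#' Spearman correlation between paired feature vectors
#'
#' @param feat_a,feat_b numeric vectors of equal length >= 4.
#' @return list with `rho` and `p` (two-sided).
#' @export
paired_spearman <- function(feat_a, feat_b) {
  if (length(feat_a) != length(feat_b) || length(feat_a) < 4)
    stop("need paired vectors of equal length >= 4")
  if (stats::sd(feat_a) < 1e-12 || stats::sd(feat_b) < 1e-12)
    stop("Spearman correlation is undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(feat_a, feat_b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
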