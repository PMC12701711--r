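#' Dice overlap of two binary masks
#'
#' `2 TP / (2 TP + FP + FN)`; defined as 1 when both masks are empty.
#'
#' @param pred,truth binary (logical or 0/1) arrays of the same shape.
#' @return Dice score in \[0, 1\].
#' @export
dice_score <- function(pred, truth) {
  p <- vol_data(pred) != 0
  t <- vol_data(truth) != 0
  stopifnot_same_shape(p, t)
  dice_binary(p, t)
}

# core on logical vectors/arrays of equal length
dice_binary <- function(p, t) {
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

dice_from_counts <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Confusion counts at a given aggregation level
#'
#' Infers slice-, stack- and region-level units from voxel-level masks:
#' \describe{
#'   \item{voxel}{per-voxel counts.}
#'   \item{slice}{a slice is positive when it contains at least `min_voxels`
#'     labeled voxels (same rule for prediction and truth).}
#'   \item{stack}{maximal runs of consecutive positive slices; a truth stack
#'     is a TP when at least `stack_tp_frac` of its slices are predicted
#'     positive, otherwise a FN; predicted stacks with no such truth overlap
#'     are FPs; TN is the count of slices positive on neither side, grouped
#'     into runs.}
#'   \item{region}{connected components become axis-aligned bounding boxes;
#'     a truth box is a TP when some predicted box overlaps it with
#'     IoU >= `region_iou`; predicted boxes overlapping no truth box are
#'     FPs. No TN is defined at this level.}
#' }
#'
#' @param pred,truth binary or labelled masks (nonzero = positive).
#' @param level `"voxel"`, `"slice"`, `"stack"` or `"region"`.
#' @param min_voxels slice positivity threshold (default 1).
#' @param stack_tp_frac slice-coverage fraction for a stack TP (default 0.5).
#' @param region_iou box IoU threshold for a region TP (default 0.25).
#' @return list with `tp`, `fp`, `fn`, `tn` (NA at region level) and `level`.
#' @export
confusion_counts <- function(pred, truth,
                             level = c("voxel", "slice", "stack", "region"),
                             min_voxels = 1, stack_tp_frac = 0.5,
                             region_iou = 0.25) {
  level <- match.arg(level)
  p <- vol_data(pred) != 0
  t <- vol_data(truth) != 0
  stopifnot_same_shape(p, t)
  if (level == "voxel") {
    return(list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
                tn = sum(!p & !t), level = level))
  }
  ps <- apply(p, 3, sum) >= min_voxels
  ts <- apply(t, 3, sum) >= min_voxels
  if (level == "slice") {
    return(list(tp = sum(ps & ts), fp = sum(ps & !ts), fn = sum(!ps & ts),
                tn = sum(!ps & !ts), level = level))
  }
  if (level == "stack") {
    truth_stacks <- slice_runs(ts)
    pred_stacks <- slice_runs(ps)
    tp <- 0L; fn <- 0L
    for (i in seq_len(nrow(truth_stacks))) {
      sl <- truth_stacks$start[i]:truth_stacks$end[i]
      if (mean(ps[sl]) >= stack_tp_frac) tp <- tp + 1L else fn <- fn + 1L
    }
    fp <- 0L
    for (i in seq_len(nrow(pred_stacks))) {
      sl <- pred_stacks$start[i]:pred_stacks$end[i]
      if (!any(ts[sl])) fp <- fp + 1L
    }
    tn <- nrow(slice_runs(!ps & !ts))
    return(list(tp = tp, fp = fp, fn = fn, tn = tn, level = level))
  }
  # region level
  tb <- component_boxes(t)
  pb <- component_boxes(p)
  tp <- 0L; fn <- 0L
  matched_pred <- rep(FALSE, length(pb))
  for (i in seq_along(tb)) {
    ious <- vapply(pb, box_iou, numeric(1), b = tb[[i]])
    hit <- which(ious >= region_iou)
    if (length(hit) > 0) { tp <- tp + 1L; matched_pred[hit] <- TRUE }
    else fn <- fn + 1L
  }
  fp <- 0L
  for (j in seq_along(pb)) {
    ious <- if (length(tb)) vapply(tb, box_iou, numeric(1), b = pb[[j]]) else 0
    if (all(ious == 0)) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = NA_integer_, level = level)
}

# maximal runs of TRUE in a logical vector
slice_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

component_boxes <- function(mask) {
  lab <- label_components(mask)
  n <- attr(lab, "n")
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) bbox_of(lab == i))
}

box_iou <- function(a, b) {
  lo <- pmax(a$lo, b$lo); hi <- pmin(a$hi, b$hi)
  if (any(hi < lo)) return(0)
  inter <- prod(hi - lo + 1)
  va <- prod(a$hi - a$lo + 1); vb <- prod(b$hi - b$lo + 1)
  inter / (va + vb - inter)
}

#' Standard metrics from confusion counts
#'
#' @param counts a [confusion_counts()] result (or list with tp/fp/fn/tn).
#' @return list with `dice`, `accuracy`, `sensitivity`, `specificity` and
#'   `youden_j` (NA where a denominator is undefined, e.g. specificity at
#'   region level).
#' @export
level_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (!is.na(tn) && tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (!is.na(tn)) (tp + tn) / (tp + fp + fn + tn) else NA_real_
  list(dice = dice_from_counts(tp, fp, fn), accuracy = acc,
       sensitivity = sens, specificity = spec,
       youden_j = if (!is.na(sens) && !is.na(spec)) sens + spec - 1 else NA_real_)
}

#' Weighted average
#'
#' Used for the weighted-by-volume and weighted-by-slices aggregates that
#' emphasize performance on larger artifacts.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, not all zero.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_average <- function(values, weights) {
  if (length(values) != length(weights)) stop("lengths differ")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (sum(weights) == 0) stop("weights must not all be zero")
  sum(values * weights) / sum(weights)
}

#' Youden's J statistic
#'
#' `sensitivity + specificity - 1`: 1 for a perfect classifier, 0 for
#' chance, negative for worse than chance.
#'
#' @param sensitivity,specificity values in \[0, 1\].
#' @return J in \[-1, 1\].
#' @export
youden_j <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) || any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Overfitting index from train/test Dice losses
#'
#' `phi = (DL_train - DL_test) / (DL_train + DL_test) + 1`, bounded between
#' 0 and 2. Values below 1 indicate overfitting to the training set (below
#' 0.85, severely so); values above 1 indicate generalization.
#'
#' @param dl_train,dl_test Dice losses in \[0, 1\], not both zero.
#' @return list with `dl_train`, `dl_test`, `phi` and `verdict`
#'   (`"over-fitting"`, `"acceptable"` or `"generalizable"`).
#' @export
overfit_index <- function(dl_train, dl_test) {
  if (dl_train < 0 || dl_train > 1 || dl_test < 0 || dl_test > 1)
    stop("Dice losses must lie in [0, 1]")
  if (dl_train + dl_test == 0)
    stop("phi is undefined when both losses are zero")
  phi <- (dl_train - dl_test) / (dl_train + dl_test) + 1
  verdict <- if (phi < 0.85) "over-fitting" else if (phi < 1) "acceptable" else "generalizable"
  list(dl_train = dl_train, dl_test = dl_test, phi = phi, verdict = verdict)
}

#' Triangle area by Heron's formula
#'
#' @param a,b,c side lengths (vectors allowed).
#' @return area(s); degenerate triangles give 0.
#' @export
heron_area <- function(a, b, c) {
  s <- (a + b + c) / 2
  sqrt(pmax(s * (s - a) * (s - b) * (s - c), 0))
}

#' Boundary smoothness of a binary mask
#'
#' Ratio `beta = S / V` of the mask's isosurface area to its volume. The
#' surface is triangulated by marching tetrahedra at level 0.5 (after an
#' optional Gaussian pre-smoothing of the binary field, which removes the
#' voxelization staircase so digital balls recover the analytic `3/r`
#' surface-to-volume ratio), restricted to `bbox`; triangle areas use
#' Heron's formula on the Euclidean vertex distances scaled by `spacing`,
#' and the volume is the voxel count times the voxel volume.
#'
#' @param mask binary 3D array (or mask object).
#' @param spacing mm per voxel (length 3).
#' @param bbox optional `list(lo, hi)` restriction (1-based inclusive).
#' @param smooth_sigma sd (voxels) of the pre-mesh Gaussian smoothing
#'   (default 1; 0 meshes the raw binary staircase).
#' @return list with `surface_area` (mm^2), `volume` (mm^3), `beta`
#'   (per mm) and `n_triangles`.
#' @export
boundary_smoothness <- function(mask, spacing = c(1, 1, 1), bbox = NULL,
                                smooth_sigma = 1) {
  b <- vol_data(mask) != 0
  if (!is.null(bbox)) b <- crop_bbox(b, bbox)
  nvox <- sum(b)
  if (nvox == 0) stop("mask is empty within the bounding box")
  tri <- isosurface_triangles(b, smooth_sigma)
  if (nrow(tri$v1) == 0) stop("no isosurface found (mask fills the box?)")
  sc <- function(m) sweep(m, 2, spacing, `*`)
  a <- sqrt(rowSums((sc(tri$v1) - sc(tri$v2))^2))
  bb <- sqrt(rowSums((sc(tri$v2) - sc(tri$v3))^2))
  cc <- sqrt(rowSums((sc(tri$v3) - sc(tri$v1))^2))
  S <- sum(heron_area(a, bb, cc))
  V <- nvox * prod(spacing)
  list(surface_area = S, volume = V, beta = S / V, n_triangles = length(a))
}

# Marching tetrahedra on a (optionally smoothed) scalar field at level 0.5.
# The field is zero-padded by one voxel so surfaces close at the boundary.
# Returns three matrices of triangle vertex coordinates (voxel units, in the
# cropped array's coordinate frame).
isosurface_triangles <- function(binary, smooth_sigma = 1, level = 0.5) {
  f <- array(as.numeric(binary), dim(binary) + 2L)
  f[] <- 0
  f[2:(dim(binary)[1] + 1), 2:(dim(binary)[2] + 1), 2:(dim(binary)[3] + 1)] <-
    as.numeric(binary)
  if (smooth_sigma > 0) f <- gauss_smooth_3d(f, smooth_sigma)
  d <- dim(f)
  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  # cell origins
  cg <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  corner_off <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                      c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  lin <- function(off) {
    (cg$x + off[1]) + (cg$y + off[2] - 1L) * d[1] +
      (cg$z + off[3] - 1L) * d[1] * d[2]
  }
  vals <- sapply(seq_len(8), function(i) f[lin(corner_off[i, ])])
  # keep only cells straddling the level
  cmin <- do.call(pmin, as.data.frame(vals))
  cmax <- do.call(pmax, as.data.frame(vals))
  act <- which(cmin < level & cmax >= level)
  if (length(act) == 0)
    return(list(v1 = matrix(0, 0, 3), v2 = matrix(0, 0, 3), v3 = matrix(0, 0, 3)))
  vals <- vals[act, , drop = FALSE]
  orig <- cbind(cg$x[act], cg$y[act], cg$z[act])
  # 6-tetra decomposition of the cube along main diagonal 1-7
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  V1 <- V2 <- V3 <- list()
  push <- function(p1, p2, p3) {
    V1[[length(V1) + 1L]] <<- p1
    V2[[length(V2) + 1L]] <<- p2
    V3[[length(V3) + 1L]] <<- p3
  }
  edge_point <- function(rows, i, j) {
    vi <- vals[cbind(rows, i)]; vj <- vals[cbind(rows, j)]
    t <- (level - vi) / (vj - vi)
    pi <- orig[rows, , drop = FALSE] +
      matrix(corner_off[i, ], length(rows), 3, byrow = TRUE)
    pj <- orig[rows, , drop = FALSE] +
      matrix(corner_off[j, ], length(rows), 3, byrow = TRUE)
    pi + t * (pj - pi)
  }
  for (t in seq_len(nrow(tets))) {
    cn <- tets[t, ]
    inside <- vals[, cn, drop = FALSE] >= level
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (length(rows) == 0) next
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      ins <- cn[bits]; outs <- cn[!bits]
      if (length(ins) == 1) {
        push(edge_point(rows, ins, outs[1]),
             edge_point(rows, ins, outs[2]),
             edge_point(rows, ins, outs[3]))
      } else if (length(ins) == 3) {
        push(edge_point(rows, outs, ins[1]),
             edge_point(rows, outs, ins[2]),
             edge_point(rows, outs, ins[3]))
      } else {
        # two in, two out: quad split into two triangles
        e13 <- edge_point(rows, ins[1], outs[1])
        e14 <- edge_point(rows, ins[1], outs[2])
        e24 <- edge_point(rows, ins[2], outs[2])
        e23 <- edge_point(rows, ins[2], outs[1])
        push(e13, e14, e24)
        push(e13, e24, e23)
      }
    }
  }
  shift <- 1  # undo zero-padding offset
  list(v1 = do.call(rbind, V1) - shift,
       v2 = do.call(rbind, V2) - shift,
       v3 = do.call(rbind, V3) - shift)
}
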