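#' Per-segment threshold profile for the interpolation detector
#'
#' The axial axis is divided into `n_segments` equally sized segments, each
#' with its own detection threshold (a maximum voxel-wise difference on the
#' normalized intensity scale). Thresholds are dimensionless in \[0, 1\].
#'
#' @param thresholds numeric vector of per-segment thresholds in (0, 1).
#' @param bounds the (lower, upper) search box used when fitting
#'   (default `c(0.2, 0.3)`).
#' @return object of class `threshold_profile`.
#' @export
threshold_profile <- function(thresholds, bounds = c(0.2, 0.3)) {
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie strictly within (0, 1)")
  structure(list(n_segments = length(thresholds),
                 thresholds = as.numeric(thresholds),
                 bounds = as.numeric(bounds)),
            class = "threshold_profile")
}

# Uniform profile helper (e.g. the epsilon profile for synthetic data).
uniform_profile <- function(p, n_segments = 10) {
  threshold_profile(rep(p, n_segments))
}

#' Axial segment of a slice index
#'
#' Maps a 1-based slice index to its 1-based segment among `n_segments`
#' equal divisions of `n_slices`, by the floor rule
#' `floor((z - 1) * n_segments / n_slices) + 1` (a slice exactly on a
#' boundary falls in the upper segment).
#'
#' @param z slice index (1-based).
#' @param n_slices total axial slices.
#' @param n_segments number of segments.
#' @return integer segment index in `1..n_segments`.
#' @export
segment_of <- function(z, n_slices, n_segments) {
  if (any(z < 1) || any(z > n_slices)) stop("slice index out of range")
  pmin(floor((z - 1) * n_segments / n_slices) + 1L, n_segments)
}

#' Maximum simulated-vs-original difference over an interval
#'
#' Simulates the interpolation artifact over the interval (same linear
#' formula as the generator) and returns the maximum over interior slices
#' and voxels of the absolute difference between the simulated and original
#' slices. A genuinely interpolated interval reproduces itself (difference
#' 0); an artifact-free interval differs by at least the noise floor.
#'
#' @param v a normalized [ct_volume()] or 3D array.
#' @param iv a [slice_interval()].
#' @return scalar max-abs difference (normalized intensity units).
#' @export
interval_difference <- function(v, iv) {
  x <- vol_data(v)
  z0 <- iv$z_start; z1 <- iv$z_end
  if (z1 < z0 + 2) stop("interval has no interior slice")
  if (z0 < 1 || z1 > dim(x)[3]) stop("interval out of bounds")
  s0 <- x[, , z0]; s1 <- x[, , z1]
  mx <- 0
  for (z in (z0 + 1L):(z1 - 1L)) {
    w1 <- (z - z0) / (z1 - z0)
    mx <- max(mx, max(abs((1 - w1) * s0 + w1 * s1 - x[, , z])))
  }
  mx
}

# Exhaustive table of interval differences: every interval of each length,
# with its max-abs simulated-vs-original difference and the segment of its
# centre slice. Computed once and reused across thresholds during fitting.
interval_diff_table <- function(v, lengths = c(3, 4), n_segments = 10) {
  x <- vol_data(v)
  nz <- dim(x)[3]
  rows <- list()
  for (L in lengths) {
    if (nz < L) next
    starts <- seq_len(nz - L + 1L)
    diffs <- vapply(starts, function(s)
      interval_difference(x, list(z_start = s, z_end = s + L - 1L)), numeric(1))
    centres <- floor((starts + starts + L - 1L) / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      z_start = starts, z_end = starts + L - 1L, max_diff = diffs,
      segment = segment_of(centres, nz, n_segments))
  }
  if (length(rows) == 0)
    return(data.frame(z_start = integer(), z_end = integer(),
                      max_diff = numeric(), segment = integer()))
  do.call(rbind, rows)
}

#' Scan candidate intervals
#'
#' Slides every interval of each requested length across the axial axis,
#' computes [interval_difference()], and keeps intervals whose difference is
#' strictly below the threshold of the segment containing the interval's
#' center slice. Segments are independent, so the result does not depend on
#' evaluation order.
#'
#' @param v normalized volume.
#' @param profile a [threshold_profile()].
#' @param lengths interval lengths to test (default `c(3, 4)`; testing the
#'   two smallest lengths suffices because subintervals of a long artifact
#'   are themselves detected and merged back together).
#' @return data.frame with columns `z_start`, `z_end`, `max_diff`, `segment`.
#' @export
scan_intervals <- function(v, profile, lengths = c(3, 4)) {
  tab <- interval_diff_table(v, lengths, profile$n_segments)
  tab[tab$max_diff < profile$thresholds[tab$segment], , drop = FALSE]
}

#' Consolidate candidate intervals
#'
#' Applies the non-containment rule (drop any interval fully contained in
#' another candidate) and then merges intervals that overlap or abut into
#' maximal runs, recovering full artifact intervals from their detected
#' subintervals. Idempotent.
#'
#' @param candidates data.frame with `z_start`, `z_end` (as from
#'   [scan_intervals()]).
#' @return data.frame with `z_start`, `z_end` of the final intervals, sorted.
#' @export
consolidate <- function(candidates) {
  if (nrow(candidates) == 0)
    return(data.frame(z_start = integer(), z_end = integer()))
  n <- nrow(candidates)
  contained <- vapply(seq_len(n), function(i) {
    any(candidates$z_start <= candidates$z_start[i] &
          candidates$z_end >= candidates$z_end[i] &
          (candidates$z_start != candidates$z_start[i] |
             candidates$z_end != candidates$z_end[i]))
  }, logical(1))
  keep <- candidates[!contained, , drop = FALSE]
  ord <- order(keep$z_start, keep$z_end)
  keep <- keep[ord, , drop = FALSE]
  out_s <- keep$z_start[1]; out_e <- keep$z_end[1]
  res <- list()
  if (nrow(keep) > 1) {
    for (i in 2:nrow(keep)) {
      if (keep$z_start[i] <= out_e + 1L) {
        out_e <- max(out_e, keep$z_end[i])
      } else {
        res[[length(res) + 1L]] <- c(out_s, out_e)
        out_s <- keep$z_start[i]; out_e <- keep$z_end[i]
      }
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(z_start = as.integer(m[, 1]), z_end = as.integer(m[, 2]))
}

#' Detect interpolation artifacts in a volume
#'
#' Runs the full rule-based detector: scan all intervals of the configured
#' lengths, keep those below the per-segment thresholds, and consolidate.
#'
#' @param v normalized [ct_volume()] or 3D array.
#' @param profile a [threshold_profile()].
#' @param lengths interval lengths to test.
#' @return object of class `interp_detection`: list with `intervals`
#'   (data.frame `z_start`, `z_end`), `slice_flags` (logical per slice,
#'   the union of detected intervals), and `profile`.
#' @export
detect_interpolation <- function(v, profile, lengths = c(3, 4)) {
  x <- vol_data(v)
  nz <- dim(x)[3]
  cand <- scan_intervals(x, profile, lengths)
  ivs <- consolidate(cand)
  flags <- logical(nz)
  for (i in seq_len(nrow(ivs))) flags[ivs$z_start[i]:ivs$z_end[i]] <- TRUE
  structure(list(intervals = ivs, slice_flags = flags, profile = profile,
                 candidates = cand),
            class = "interp_detection")
}

#' @export
print.interp_detection <- function(x, ...) {
  cat(sprintf("<interp_detection> %d interval(s), %d flagged slice(s)\n",
              nrow(x$intervals), sum(x$slice_flags)))
  if (nrow(x$intervals) > 0) print(x$intervals)
  invisible(x)
}

# truth slice flags from a case (truth_slices logical, or artifact mask label 2)
truth_flags_of <- function(case, nz) {
  if (!is.null(case$truth_slices)) {
    flags <- case$truth_slices
  } else if (!is.null(case$mask)) {
    flags <- apply(vol_data(case$mask) == 2L, 3, any)
  } else stop("case must carry `truth_slices` or `mask`")
  if (length(flags) != nz) stop("truth flags length mismatch")
  flags
}

# Ensure a case carries its precomputed interval table, slice count and
# truth flags (so threshold sweeps never touch the voxel data again).
case_with_table <- function(case, n_segments, lengths) {
  if (is.null(case$table)) {
    case$nz <- dim(vol_data(case$volume))[3]
    case$table <- interval_diff_table(case$volume, lengths, n_segments)
  }
  if (is.null(case$truth_slices))
    case$truth_slices <- truth_flags_of(case, case$nz)
  case
}

# Slice-level Dice of one case restricted to segment `segment` at threshold p.
case_segment_dice <- function(case, segment, p, n_segments, lengths) {
  case <- case_with_table(case, n_segments, lengths)
  nz <- case$nz
  cand <- case$table[case$table$max_diff < p & case$table$segment == segment,
                     , drop = FALSE]
  det <- logical(nz)
  if (nrow(cand) > 0) {
    ivs <- consolidate(cand)
    for (i in seq_len(nrow(ivs))) det[ivs$z_start[i]:ivs$z_end[i]] <- TRUE
  }
  truth <- truth_flags_of(case, nz)
  segs <- segment_of(seq_len(nz), nz, n_segments)
  in_seg <- segs == segment
  tp <- sum(det & truth & in_seg)
  fp <- sum(det & !truth & in_seg)
  fn <- sum(!det & truth & in_seg)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Mean slice-level Dice of a segment at a threshold
#'
#' Runs detection restricted to one axial segment at threshold `p` on each
#' labeled case and returns the mean slice-level Dice against the ground
#' truth. Cases whose segment contains no ground-truth interpolated slices
#' still contribute (false positives there lower the Dice); a segment with
#' no ground truth in any case triggers a warning.
#'
#' @param cases list of cases, each a list with `volume` (normalized volume)
#'   and either `truth_slices` (logical per slice) or `mask` (an
#'   [artifact_mask()] with label 2 on interpolated slices).
#' @param segment 1-based segment index.
#' @param p threshold.
#' @param n_segments number of axial segments.
#' @param lengths interval lengths to test.
#' @return mean Dice over the cases.
#' @export
dice_for_threshold <- function(cases, segment, p, n_segments = 10,
                               lengths = c(3, 4)) {
  any_truth <- any(vapply(cases, function(cs) {
    nz <- dim(vol_data(cs$volume))[3]
    truth <- truth_flags_of(cs, nz)
    any(truth & segment_of(seq_len(nz), nz, n_segments) == segment)
  }, logical(1)))
  if (!any_truth)
    warning(sprintf("segment %d has no ground-truth intervals in any case", segment))
  mean(vapply(cases, case_segment_dice, numeric(1),
              segment = segment, p = p, n_segments = n_segments,
              lengths = lengths))
}

segment_has_truth <- function(cases, segment, n_segments) {
  any(vapply(cases, function(cs) {
    nz <- dim(vol_data(cs$volume))[3]
    truth <- truth_flags_of(cs, nz)
    any(truth & segment_of(seq_len(nz), nz, n_segments) == segment)
  }, logical(1)))
}

# minimize mean Dice loss over (lo, hi) for one segment
optimize_segment <- function(cases, segment, bounds, method, grid_step,
                             n_segments, lengths) {
  loss <- function(p) 1 - dice_for_threshold(cases, segment, p,
                                             n_segments, lengths)
  if (method == "grid") {
    grid <- seq(bounds[1] + grid_step, bounds[2] - grid_step / 2, by = grid_step)
    vals <- vapply(grid, loss, numeric(1))
    grid[which.min(vals)]
  } else {
    stats::optimize(loss, interval = bounds, tol = grid_step / 2)$minimum
  }
}

#' Fit per-segment detection thresholds from labeled cases
#'
#' Fits the rule-based interpolation detector by solving, independently for
#' each axial segment, the bounded scalar problem: minimize the mean Dice
#' loss of the detector over the segment's intervals, within the search
#' bounds (default 0.2 to 0.3), via brute-force grid search or bounded
#' scalar (Brent) optimization. k-fold cross-validation reports the held-out
#' Dice per fold; the final thresholds are fitted on all cases. A segment
#' with no ground-truth intervals falls back to the across-segment median of
#' the fitted thresholds (with a message).
#'
#' @param cases list of labeled cases (see [dice_for_threshold()]).
#' @param n_segments number of axial segments (default 10).
#' @param bounds threshold search bounds (default `c(0.2, 0.3)`).
#' @param method `"grid"` or `"brent"`.
#' @param grid_step grid resolution (default 0.002).
#' @param n_folds folds for cross-validation (default 10; reduced to the
#'   number of cases when there are fewer).
#' @param lengths interval lengths to test.
#' @param seed seed for the fold assignment.
#' @return An object of class `interp_detector`: the fitted
#'   [threshold_profile()] plus the cross-validation table and fit metadata.
#'   Methods: [print()], [summary()], [coef()] (the thresholds),
#'   [predict()] (runs detection on a new volume), [plot()].
#' @export
fit_interp_detector <- function(cases, n_segments = 10, bounds = c(0.2, 0.3),
                                method = c("grid", "brent"), grid_step = 0.002,
                                n_folds = 10, lengths = c(3, 4), seed = 1L) {
  method <- match.arg(method)
  if (length(cases) < 1) stop("at least one labeled case is required")
  cases <- lapply(cases, case_with_table, n_segments = n_segments,
                  lengths = lengths)
  populated <- vapply(seq_len(n_segments), segment_has_truth, logical(1),
                      cases = cases, n_segments = n_segments)
  if (!any(populated)) stop("no segment has ground-truth intervals")

  fit_all <- function(cs) {
    pop <- vapply(seq_len(n_segments), segment_has_truth, logical(1),
                  cases = cs, n_segments = n_segments)
    if (!any(pop)) stop("no segment has ground truth in this subset")
    th <- rep(NA_real_, n_segments)
    for (s in which(pop))
      th[s] <- optimize_segment(cs, s, bounds, method, grid_step,
                                n_segments, lengths)
    if (any(!pop)) {
      message(sprintf("%d segment(s) without ground truth; using the median fitted threshold",
                      sum(!pop)))
      th[!pop] <- stats::median(th[pop])
    }
    th
  }

  k <- min(n_folds, length(cases))
  cv <- NULL
  if (k >= 2) {
    folds <- with_seed(seed, sample(rep_len(seq_len(k), length(cases))))
    held_dice <- numeric(k)
    for (f in seq_len(k)) {
      tr <- cases[folds != f]; te <- cases[folds == f]
      th_f <- tryCatch(fit_all(tr), error = function(e) NULL)
      if (is.null(th_f)) { held_dice[f] <- NA; next }
      prof_f <- threshold_profile(th_f, bounds)
      d <- vapply(te, function(cs) {
        nz <- dim(vol_data(cs$volume))[3]
        det <- detect_interpolation(cs$volume, prof_f, lengths)
        dice_binary(det$slice_flags, truth_flags_of(cs, nz))
      }, numeric(1))
      held_dice[f] <- mean(d)
    }
    cv <- data.frame(fold = seq_len(k), held_out_dice = held_dice)
  }

  th <- fit_all(cases)
  structure(list(thresholds = th, bounds = bounds, n_segments = n_segments,
                 method = method, grid_step = grid_step, lengths = lengths,
                 cv = cv, n_cases = length(cases),
                 populated = populated, call = match.call()),
            class = "interp_detector")
}

#' @export
print.interp_detector <- function(x, ...) {
  cat("Rule-based interpolation-artifact detector\n")
  cat(sprintf("  %d axial segments, thresholds fitted in (%.3g, %.3g) by %s\n",
              x$n_segments, x$bounds[1], x$bounds[2], x$method))
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.interp_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  fitted on %d case(s); %d/%d segments had ground truth\n",
              object$n_cases, sum(object$populated), object$n_segments))
  if (!is.null(object$cv)) {
    cat(sprintf("  %d-fold CV held-out Dice: mean %.4f (min %.4f)\n",
                nrow(object$cv), mean(object$cv$held_out_dice, na.rm = TRUE),
                min(object$cv$held_out_dice, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
coef.interp_detector <- function(object, ...) {
  stats::setNames(object$thresholds,
                  paste0("segment", seq_len(object$n_segments)))
}

#' Detect artifacts in a new volume with a fitted detector
#'
#' @param object a fitted [fit_interp_detector()] object.
#' @param newdata a normalized volume.
#' @param ... unused.
#' @return an `interp_detection` (see [detect_interpolation()]).
#' @export
predict.interp_detector <- function(object, newdata, ...) {
  detect_interpolation(newdata,
                       threshold_profile(object$thresholds, object$bounds),
                       object$lengths)
}

#' @export
plot.interp_detector <- function(x, ...) {
  graphics::plot(seq_len(x$n_segments), x$thresholds, type = "h", lwd = 3,
                 xlab = "axial segment", ylab = "threshold",
                 ylim = range(c(x$bounds, x$thresholds)), ...)
  graphics::abline(h = x$bounds, lty = 2, col = "grey50")
  invisible(x)
}
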