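#' Truncate HU intensities and normalize to \[0, 1\]
#'
#' Clips intensities to the CT window \[-1024, 600\] HU and maps the clipped
#' range linearly onto \[0, 1\] (divisor 1624, so the window endpoints map
#' exactly to 0 and 1). All downstream generators and the detector operate on
#' this normalized scale.
#'
#' @param v a [ct_volume()] in the HU domain.
#' @return a [ct_volume()] with `domain = "normalized"`.
#' @examples
#' v <- ct_volume(array(c(-1024, -212, 600), c(1, 1, 3)))
#' range(truncate_and_normalize(v)$data)
#' @export
truncate_and_normalize <- function(v) {
  if (!inherits(v, "ct_volume")) stop("`v` must be a ct_volume")
  if (v$domain == "normalized") {
    warning("volume is already normalized; returning it unchanged")
    return(v)
  }
  x <- pmin(pmax(v$data, -1024), 600)
  x <- (x + 1024) / 1624
  ct_volume(array(x, dim(v$data)), v$spacing, v$phase, "normalized")
}

#' Crop a volume and its lung mask to the lung bounding box
#'
#' Crops both grids to the tight axis-aligned bounding box of the nonzero
#' mask voxels, expanded by `margin` voxels and clamped to the grid. The
#' returned `offset` is the 1-based index of the crop origin in the original
#' grid, so `original[offset + i - 1] == cropped[i]`.
#'
#' @param v a [ct_volume()].
#' @param m the paired [lung_mask()] (nonempty).
#' @param margin expansion in voxels (default 5, keeping peri-lung tissue for
#'   the phase-binning generator).
#' @return list with `volume`, `mask` and `offset` (length-3 integer).
#' @export
crop_to_lungs <- function(v, m, margin = 5) {
  stopifnot_same_shape(v, m)
  bb <- bbox_of(m$data)
  if (is.null(bb)) stop("lung mask is empty; nothing to crop to")
  bb <- expand_bbox(bb, margin, dim(v$data))
  list(volume = ct_volume(crop_bbox(v$data, bb), v$spacing, v$phase, v$domain),
       mask = lung_mask(crop_bbox(m$data, bb), m$spacing),
       offset = as.integer(bb$lo))
}

#' Region-based mask from a lung mask
#'
#' The region-based mask restricts artifact detection and learning to the
#' peri-lung region: the binary union of both lungs morphologically dilated
#' by a Euclidean ball.
#'
#' @param m a [lung_mask()].
#' @param dilation_voxels ball radius in voxels (default 3).
#' @return logical 3D array (a superset of the lung voxels).
#' @export
make_region_mask <- function(m, dilation_voxels = 3) {
  if (sum(m$data > 0) == 0) stop("lung mask is empty")
  dilate_ball(m$data > 0, dilation_voxels)
}

#' Split a case into independently cropped left and right lungs
#'
#' Crops the volume and mask to each lung label's own bounding box, doubling
#' the number of usable cases.
#'
#' @param v a [ct_volume()].
#' @param m the paired [lung_mask()].
#' @param margin crop margin in voxels.
#' @return named list with elements `left` and/or `right`, each a
#'   `list(volume, mask, offset)`; a missing lung label drops that side with
#'   a warning.
#' @export
split_left_right <- function(v, m, margin = 0) {
  stopifnot_same_shape(v, m)
  out <- list()
  for (side in 1:2) {
    nm <- c("left", "right")[side]
    sub <- array(ifelse(m$data == side, side, 0L), dim(m$data))
    bb <- bbox_of(sub)
    if (is.null(bb)) {
      warning(sprintf("no %s lung label present; emitting only the other side", nm))
      next
    }
    bb <- expand_bbox(bb, margin, dim(v$data))
    out[[nm]] <- list(volume = ct_volume(crop_bbox(v$data, bb), v$spacing,
                                         v$phase, v$domain),
                      mask = lung_mask(crop_bbox(sub, bb), m$spacing),
                      offset = as.integer(bb$lo))
  }
  out
}
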