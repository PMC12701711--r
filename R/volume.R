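#' 3D CT volume container
#'
#' Lightweight container for one breathing-phase 3D intensity grid. Axis order
#' is (x, y, z) with z the axial (slice) axis; indices are 1-based throughout
#' the package. Intensities live either on the Hounsfield-unit scale
#' (`domain = "HU"`) or on the normalized \[0, 1\] scale produced by
#' [truncate_and_normalize()].
#'
#' @param data numeric 3D array of voxel intensities.
#' @param spacing numeric length-3 vector, mm per voxel along (x, y, z).
#' @param phase phase label such as `"T00"`, or `NA` when not tied to a phase.
#' @param domain `"HU"` or `"normalized"`.
#' @return An object of class `ct_volume`: a list with elements `data`,
#'   `spacing`, `phase` and `domain`.
#' @examples
#' v <- ct_volume(array(0, c(16, 16, 16)))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), phase = NA_character_,
                      domain = c("HU", "normalized")) {
  domain <- match.arg(domain)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (domain == "normalized" && (min(data) < 0 || max(data) > 1))
    stop("normalized volumes must lie in [0, 1]")
  structure(list(data = data, spacing = as.numeric(spacing),
                 phase = phase, domain = domain),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, spacing %s mm, phase %s, %s [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              ifelse(is.na(x$phase), "-", x$phase), x$domain,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Labelled lung mask container
#'
#' Label grid paired with a [ct_volume()]: 0 = background, 1 = left lung,
#' 2 = right lung.
#'
#' @param data integer-valued 3D array with values in \{0, 1, 2\}.
#' @param spacing mm per voxel along (x, y, z).
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(data %in% c(0, 1, 2)))
    stop("lung mask labels must be 0 (background), 1 (left) or 2 (right)")
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = as.numeric(spacing)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lung_mask> %dx%dx%d, left %d vox, right %d vox\n",
              d[1], d[2], d[3], sum(x$data == 1L), sum(x$data == 2L)))
  invisible(x)
}

#' Artifact ground-truth / prediction mask container
#'
#' Per-voxel artifact labels: 0 = none, 1 = phase-binning, 2 = interpolation.
#' The union of the nonzero labels is the overall artifact mask.
#'
#' @param data integer-valued 3D array with values in \{0, 1, 2\}.
#' @return An object of class `artifact_mask`.
#' @export
artifact_mask <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(data %in% c(0, 1, 2)))
    stop("artifact labels must be 0 (none), 1 (phase-binning) or 2 (interpolation)")
  structure(list(data = array(as.integer(data), dim(data))),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %s, phase-binning %d vox, interpolation %d vox\n",
              paste(dim(x$data), collapse = "x"),
              sum(x$data == 1L), sum(x$data == 2L)))
  invisible(x)
}

# Coerce array / ct_volume to a bare 3D array.
vol_data <- function(v) {
  if (inherits(v, c("ct_volume", "lung_mask", "artifact_mask"))) v$data else v
}

vol_spacing <- function(v, default = c(1, 1, 1)) {
  if (inherits(v, c("ct_volume", "lung_mask")) && !is.null(v$spacing)) v$spacing
  else default
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop("volumes/masks must share the same grid shape")
  invisible(TRUE)
}
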