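#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param domain intensity domain to tag the volume with (`"HU"` or
#'   `"normalized"`; guessed from the value range when NULL).
#' @return a [ct_volume()] with spacing taken from the NIfTI pixdim.
#' @export
read_volume <- function(path, domain = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img)[1:3])
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(domain))
    domain <- if (min(data) >= 0 && max(data) <= 1) "normalized" else "HU"
  ct_volume(data, spacing, domain = domain)
}

#' Write a volume to NIfTI
#'
#' @param v a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  x <- v$data
  attr(x, "pixdim") <- v$spacing
  RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), path)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' @param path path to the mask file.
#' @param kind `"lung"` or `"artifact"`.
#' @return a [lung_mask()] or [artifact_mask()].
#' @export
read_mask <- function(path, kind = c("lung", "artifact")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- array(as.integer(round(as.numeric(img))), dim(img)[1:3])
  if (kind == "lung") lung_mask(data, RNifti::pixdim(img)[1:3])
  else artifact_mask(data)
}

# Label masks are written as unsigned 8-bit.
write_mask <- function(data, spacing, path) {
  x <- array(as.integer(data), dim(data))
  attr(x, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(x, datatype = "uint8"), path)
  invisible(path)
}

#' Write a phantom series to disk
#'
#' Writes each phase volume and mask as NIfTI
#' (`<case>_T##_{img|lung}.nii.gz`) plus a JSON manifest recording the spec.
#'
#' @param series a [generate_phase_series()] result.
#' @param dir output directory.
#' @param case case name prefix.
#' @return the manifest path, invisibly.
#' @export
write_phase_series <- function(series, dir, case = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in series$phases) {
    write_volume(p$volume, file.path(dir, sprintf("%s_%s_img.nii.gz", case, p$label)))
    write_mask(p$mask$data, p$mask$spacing,
               file.path(dir, sprintf("%s_%s_lung.nii.gz", case, p$label)))
  }
  manifest <- file.path(dir, sprintf("%s_manifest.json", case))
  jsonlite::write_json(unclass(series$spec), manifest, auto_unbox = TRUE)
  invisible(manifest)
}
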