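#' Construct a slice interval
#'
#' A contiguous axial slice range with at least one interior slice
#' (`z_end >= z_start + 2`), 1-based and inclusive.
#'
#' @param z_start first slice index.
#' @param z_end last slice index.
#' @return list with `z_start`, `z_end`, `length`.
#' @export
slice_interval <- function(z_start, z_end) {
  if (z_end < z_start + 2)
    stop("interval must contain at least one interior slice (z_end >= z_start + 2)")
  list(z_start = as.integer(z_start), z_end = as.integer(z_end),
       length = as.integer(z_end - z_start + 1L))
}

#' Linearly interpolate the interior slices of an interval
#'
#' Replaces each interior axial slice z of the interval \[z0, z1\] by the
#' distance-weighted combination of the endpoint slices,
#' `((z1 - z)/(z1 - z0)) * I[z0] + ((z - z0)/(z1 - z0)) * I[z1]`,
#' smearing the anatomy between the two couch positions. Endpoint slices and
#' all slices outside the interval are unchanged. The same routine is used
#' by the generator (to infuse artifacts) and by the detector (to simulate
#' them).
#'
#' @param v a [ct_volume()] or 3D array.
#' @param iv a [slice_interval()] (or list with `z_start`, `z_end`).
#' @return same type as `v`, with the interval's interior slices replaced.
#' @export
interpolate_interval <- function(v, iv) {
  x <- vol_data(v)
  nz <- dim(x)[3]
  z0 <- iv$z_start; z1 <- iv$z_end
  if (z0 < 1 || z1 > nz) stop("interval out of bounds")
  if (z1 < z0 + 2) stop("interval must contain at least one interior slice")
  s0 <- x[, , z0]; s1 <- x[, , z1]
  for (z in (z0 + 1L):(z1 - 1L)) {
    w1 <- (z - z0) / (z1 - z0)
    x[, , z] <- (1 - w1) * s0 + w1 * s1
  }
  if (inherits(v, "ct_volume")) ct_volume(x, v$spacing, v$phase, v$domain) else x
}

#' Draw perturbed interpolation intervals
#'
#' Places `n_intervals` non-overlapping seed intervals of length `h`
#' uniformly at random anywhere along the axial axis (interpolation
#' artifacts are not restricted to a lung region), then perturbs each
#' endpoint by `round(rnorm(1, 0, sigma_g))`, clamping to the volume bounds
#' and to a minimum length of 3. Intervals that overlap or abut after
#' perturbation are merged.
#'
#' @param params list with `h`, `n_intervals`, `sigma_g`, `seed` (see
#'   [interp_params()]).
#' @param n_slices axial slice count of the target volume.
#' @return list of [slice_interval()]s (possibly fewer than requested after
#'   merging), sorted by `z_start`.
#' @export
perturb_intervals <- function(params, n_slices) {
  h <- params$h; n <- params$n_intervals; sg <- params$sigma_g
  if (n == 0) return(list())
  if (h < 3) stop("initial interval length h must be >= 3")
  if (n * h > n_slices) stop("cannot place intervals without overlap")
  with_seed(params$seed, {
    ok <- FALSE
    for (try in 1:200) {
      starts <- sort(sample(seq_len(n_slices - h + 1L), n, replace = TRUE))
      if (n == 1L || all(diff(starts) >= h)) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place intervals without overlap")
    iv <- lapply(starts, function(s) {
      a <- s + round(stats::rnorm(1, 0, sg))
      b <- s + h - 1L + round(stats::rnorm(1, 0, sg))
      a <- max(1L, min(a, n_slices - 2L))
      b <- min(n_slices, max(b, a + 2L))
      slice_interval(a, b)
    })
    merge_intervals(iv)
  })
}

#' Interpolation generator parameters
#'
#' @param h initial interval length in slices (>= 3).
#' @param n_intervals number of intervals to insert (>= 0).
#' @param sigma_g Gaussian sd (slices) of the endpoint perturbation (>= 0).
#' @param seed RNG seed.
#' @return list of class `interp_params`.
#' @export
interp_params <- function(h = 8, n_intervals = 1, sigma_g = 1, seed = 1L) {
  if (n_intervals < 0) stop("n_intervals must be >= 0")
  if (sigma_g < 0) stop("sigma_g must be >= 0")
  structure(list(h = as.integer(h), n_intervals = as.integer(n_intervals),
                 sigma_g = sigma_g, seed = as.integer(seed)),
            class = "interp_params")
}

# Merge a list of intervals that overlap or abut; input need not be sorted.
merge_intervals <- function(ivs) {
  if (length(ivs) == 0) return(list())
  ord <- order(vapply(ivs, `[[`, 1L, "z_start"))
  ivs <- ivs[ord]
  out <- list(ivs[[1]])
  for (iv in ivs[-1]) {
    lastv <- out[[length(out)]]
    if (iv$z_start <= lastv$z_end + 1L) {
      out[[length(out)]] <- slice_interval(lastv$z_start,
                                           max(lastv$z_end, iv$z_end))
    } else out <- c(out, list(iv))
  }
  out
}

#' Infuse interpolation artifacts
#'
#' Applies [interpolate_interval()] for each interval and labels every axial
#' slice within each final interval (endpoints included) as interpolation
#' (label 2) in the ground-truth mask.
#'
#' @param v a [ct_volume()].
#' @param intervals list of [slice_interval()]s (non-overlapping after
#'   merging; overlapping input is an error).
#' @return list with `volume` (infused) and `mask` (an [artifact_mask()]).
#' @export
infuse_interpolation <- function(v, intervals) {
  x <- vol_data(v)
  d <- dim(x)
  mask <- array(0L, d)
  if (length(intervals) > 0) {
    merged <- merge_intervals(intervals)
    if (length(merged) != length(intervals))
      stop("intervals overlap after merging; merge them first")
    for (iv in intervals) {
      v <- interpolate_interval(v, iv)
      mask[, , iv$z_start:iv$z_end] <- 2L
    }
  }
  list(volume = v, mask = artifact_mask(mask))
}
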