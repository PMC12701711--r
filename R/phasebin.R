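#' Parameters of the phase-binning artifact generator
#'
#' @param h uniform stack height in slices (>= 1).
#' @param n_stacks number of stacks to infuse from the secondary phase (>= 1).
#' @param sigma_g artifact visibility: the Gaussian sd (in slices) used to
#'   feather the binary slice mask. Small values (< 1) give sharp, pronounced
#'   artifacts; large values give larger, more faded ones.
#' @param shift_intensity maximum in-plane displacement (voxels) applied to
#'   the secondary phase's stack slices.
#' @param lambda0 proportionality constant of the binarization threshold
#'   `lambda = lambda0 * sigma_g` (normalized intensity units) used when
#'   deriving the ground-truth mask.
#' @param min_component smallest connected component (voxels) retained in the
#'   ground-truth mask.
#' @param r_close radius (voxels) of the ball used for morphological closing.
#' @param max_retries redraws of stack placement/shift when the admissibility
#'   condition fails.
#' @param seed integer RNG seed.
#' @return An object of class `pb_params`.
#' @export
pb_params <- function(h = 8, n_stacks = 1, sigma_g = 1.5, shift_intensity = 2,
                      lambda0 = 0.05, min_component = 50, r_close = 2,
                      max_retries = 5, seed = 1L) {
  if (h < 1) stop("h must be >= 1")
  if (n_stacks < 1) stop("n_stacks must be >= 1")
  if (sigma_g <= 0) stop("sigma_g must be > 0")
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  structure(list(h = as.integer(h), n_stacks = as.integer(n_stacks),
                 sigma_g = sigma_g, shift_intensity = as.integer(shift_intensity),
                 lambda0 = lambda0, min_component = min_component,
                 r_close = r_close, max_retries = max_retries,
                 seed = as.integer(seed)),
            class = "pb_params")
}

#' Place the binary stack mask in the inferior half of the lungs
#'
#' Draws `n_stacks` non-overlapping stacks of height `h`, uniformly at random
#' within the axial range from the lung's lowest slice to the midpoint of its
#' extent (phase-binning artifacts concentrate near the diaphragm). Every
#' stack slice index is `<=` that midpoint.
#'
#' @param n_slices number of axial slices in the volume.
#' @param params a [pb_params()].
#' @param lung a [lung_mask()] (nonempty) defining the axial lung extent.
#' @param seed optional seed overriding `params$seed`.
#' @return An object of class `stack_mask`: list with `binary_profile`
#'   (length `n_slices` 0/1), `feathered_profile` (initially equal to the
#'   binary profile), and `stacks` (data.frame `z_start`, `height`).
#' @export
build_stack_mask <- function(n_slices, params, lung, seed = params$seed) {
  zr <- range(which(apply(vol_data(lung) > 0, 3, any)))
  if (!is.finite(zr[1])) stop("lung mask is empty")
  z_lo <- zr[1]
  z_mid <- floor((zr[1] + zr[2]) / 2)
  max_start <- z_mid - params$h + 1L
  if (max_start < z_lo)
    stop("stack height does not fit in the inferior half of the lung extent")
  n_pos <- max_start - z_lo + 1L
  if (params$n_stacks * params$h > n_pos + params$h - 1L)
    stop("requested stacks cannot fit without overlap")
  with_seed(seed, {
    ok <- FALSE
    for (try in 1:200) {
      starts <- sort(sample(z_lo:max_start, params$n_stacks, replace = TRUE))
      if (params$n_stacks == 1L ||
          all(diff(starts) >= params$h)) { ok <- TRUE; break }
    }
    if (!ok) stop("requested stacks cannot fit without overlap")
    prof <- numeric(n_slices)
    for (s in starts) prof[s:(s + params$h - 1L)] <- 1
    structure(list(binary_profile = prof, feathered_profile = prof,
                   stacks = data.frame(z_start = starts, height = params$h)),
              class = "stack_mask")
  })
}

#' Feather the binary stack mask along z
#'
#' Smooths the binary slice profile with a 1D Gaussian kernel of sd
#' `sigma_g`, then renormalizes so the maximum over each stack equals 1 (so
#' visibility is not attenuated for large `sigma_g`; stacks instead gain a
#' few faded slices at their edges).
#'
#' @param sm a [build_stack_mask()] result.
#' @param sigma_g Gaussian sd in slices.
#' @return the `stack_mask` with `feathered_profile` filled in (values in
#'   \[0, 1\]).
#' @export
feather_stack_mask <- function(sm, sigma_g) {
  prof <- convolve_replicate(sm$binary_profile, gauss_kernel_1d(sigma_g))
  nz <- length(prof)
  if (nrow(sm$stacks) > 0 && max(prof) > 0) {
    # renormalize per stack: each z belongs to the nearest stack centre
    centres <- sm$stacks$z_start + (sm$stacks$height - 1) / 2
    nearest <- vapply(seq_len(nz), function(z) which.min(abs(centres - z)), 1L)
    for (k in seq_len(nrow(sm$stacks))) {
      zone <- nearest == k
      slices <- sm$stacks$z_start[k]:(sm$stacks$z_start[k] + sm$stacks$height[k] - 1)
      peak <- max(prof[slices])
      if (peak > 0) prof[zone] <- prof[zone] / peak
    }
  }
  sm$feathered_profile <- pmin(pmax(prof, 0), 1)
  sm
}

#' Shift the secondary phase's stack slices in-plane
#'
#' For each stack, draws one integer offset pair uniformly from
#' \[-si, si\]^2 and translates all of the stack's axial slices in the
#' coronal/sagittal (x, y) directions with edge-replicated fill, mimicking
#' reconstruction error near the diaphragm. Slices outside stacks are
#' untouched.
#'
#' @param v the secondary-phase [ct_volume()] (normalized).
#' @param sm a `stack_mask`.
#' @param si maximum displacement in voxels (>= 0).
#' @param seed RNG seed.
#' @return the shifted [ct_volume()].
#' @export
shift_secondary <- function(v, sm, si, seed = 1L) {
  if (si < 0) stop("shift intensity must be >= 0")
  x <- vol_data(v)
  d <- dim(x)
  out <- x
  with_seed(seed, {
    for (k in seq_len(nrow(sm$stacks))) {
      off <- sample(seq(-si, si), 2, replace = TRUE)
      if (all(off == 0)) next
      slices <- sm$stacks$z_start[k]:
        min(sm$stacks$z_start[k] + sm$stacks$height[k] - 1L, d[3])
      ix <- pmin(pmax(seq_len(d[1]) - off[1], 1L), d[1])
      iy <- pmin(pmax(seq_len(d[2]) - off[2], 1L), d[2])
      out[, , slices] <- x[ix, iy, slices]
    }
  })
  if (inherits(v, "ct_volume")) ct_volume(out, v$spacing, v$phase, v$domain) else out
}

#' Check the admissibility condition for blending
#'
#' Forms the weighted difference `C = w(z) * (I - Ig)` (the feathered profile
#' broadcast over each axial slice) and accepts the pairing only when the
#' count of voxels with `C <= 0` strictly exceeds the count with `C >= 0`,
#' i.e. the majority of weighted differences are negative. This guarantees
#' the blended image contains plausible phase-binning artifacts (repeated
#' rather than missing diaphragmatic tissue).
#'
#' @param I the clean primary-phase volume (array or `ct_volume`).
#' @param Ig the (shifted) secondary-phase volume, same shape.
#' @param sm a `stack_mask` with `feathered_profile`.
#' @return list with `C` (3D array), `n_nonpositive`, `n_nonnegative` and
#'   `admissible`.
#' @export
check_admissibility <- function(I, Ig, sm) {
  a <- vol_data(I); b <- vol_data(Ig)
  stopifnot_same_shape(a, b)
  w <- sm$feathered_profile
  if (length(w) != dim(a)[3]) stop("profile length must match slice count")
  C <- sweep(a - b, 3, w, `*`)
  n_np <- sum(C <= 0)
  n_nn <- sum(C >= 0)
  list(C = C, n_nonpositive = n_np, n_nonnegative = n_nn,
       admissible = n_np > n_nn)
}

#' Blend primary and secondary phases through the feathered mask
#'
#' Computes the composite `Ihat = I * (1 - w) + w * Ig` with the feathered
#' per-slice weights broadcast over each axial slice. A per-voxel convex
#' combination, so values stay within the two inputs' range.
#'
#' @inheritParams check_admissibility
#' @return the blended volume (same type as `I`).
#' @export
blend_stack <- function(I, Ig, sm) {
  a <- vol_data(I); b <- vol_data(Ig)
  stopifnot_same_shape(a, b)
  w <- sm$feathered_profile
  out <- sweep(a, 3, 1 - w, `*`) + sweep(b, 3, w, `*`)
  if (inherits(I, "ct_volume")) ct_volume(out, I$spacing, I$phase, I$domain) else out
}

#' Derive the ground-truth phase-binning artifact mask
#'
#' Binarizes the absolute difference `|I - Ihat|` at the visibility-
#' proportional threshold `lambda = lambda0 * sigma_g`, applies 3D
#' morphological closing (ball radius `r_close`), removes connected
#' components smaller than `min_component`, and restricts the result to the
#' feathered stack support (artifacts never extend outside infused stacks).
#'
#' @param I clean normalized volume.
#' @param Ihat blended volume.
#' @param params a [pb_params()].
#' @param sm optional `stack_mask`; when supplied the mask is clipped to the
#'   slices where the feathered profile is positive.
#' @return an [artifact_mask()] with phase-binning voxels labelled 1.
#' @export
derive_pb_mask <- function(I, Ihat, params, sm = NULL) {
  a <- vol_data(I); b <- vol_data(Ihat)
  stopifnot_same_shape(a, b)
  lambda <- params$lambda0 * params$sigma_g
  if (lambda >= 1)
    stop("threshold lambda = lambda0 * sigma_g >= 1: mask would be empty by construction")
  m <- abs(a - b) > lambda
  if (any(m)) {
    m <- close_ball(m, params$r_close)
    m <- filter_small_components(m, params$min_component)
  }
  if (!is.null(sm)) {
    keep <- sm$feathered_profile > 0
    m <- sweep(m, 3, keep, `&`)
  }
  artifact_mask(array(as.integer(m), dim(a)))
}

#' Infuse phase-binning artifacts into a clean phase
#'
#' Full generator pipeline: place stacks in the inferior lung half, feather
#' the slice mask, shift the secondary phase's stack slices in-plane, check
#' the admissibility condition, blend, and derive the ground-truth mask. If
#' the admissibility condition fails, stack placement and shifts are redrawn
#' up to `max_retries` times; a persistent failure is reported as a
#' rejection (not an error), so callers can pick a different secondary phase.
#'
#' @param I clean primary-phase [ct_volume()] (normalized).
#' @param Isecondary secondary-phase [ct_volume()] (normalized, same grid).
#' @param lung the primary phase's [lung_mask()].
#' @param params a [pb_params()].
#' @return list with `accepted` (logical); when accepted also `volume` (the
#'   composite), `mask` (the [artifact_mask()]), `stack_mask`, and the
#'   admissibility counts; when rejected, the last admissibility check.
#' @export
infuse_phase_binning <- function(I, Isecondary, lung, params) {
  if (!inherits(I, "ct_volume") || I$domain != "normalized")
    stop("primary volume must be normalized")
  if (!inherits(Isecondary, "ct_volume") || Isecondary$domain != "normalized")
    stop("secondary volume must be normalized")
  stopifnot_same_shape(I, Isecondary)
  nz <- dim(I$data)[3]
  last <- NULL
  for (attempt in 0:params$max_retries) {
    s_attempt <- derive_seed(params$seed, "pb_attempt", attempt)
    sm <- build_stack_mask(nz, params, lung, seed = s_attempt)
    sm <- feather_stack_mask(sm, params$sigma_g)
    Ig <- shift_secondary(Isecondary, sm, params$shift_intensity,
                          seed = derive_seed(s_attempt, "shift"))
    adm <- check_admissibility(I, Ig, sm)
    last <- adm
    if (adm$admissible) {
      Ihat <- blend_stack(I, Ig, sm)
      mask <- derive_pb_mask(I, Ihat, params, sm)
      return(list(accepted = TRUE, volume = Ihat, mask = mask,
                  stack_mask = sm, n_nonpositive = adm$n_nonpositive,
                  n_nonnegative = adm$n_nonnegative, attempts = attempt + 1L))
    }
  }
  list(accepted = FALSE, n_nonpositive = last$n_nonpositive,
       n_nonnegative = last$n_nonnegative, attempts = params$max_retries + 1L)
}
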