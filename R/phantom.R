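#' Specification of the synthetic breathing phantom
#'
#' Defines the multi-phase lung phantom used throughout the package as a
#' stand-in for clinical 4DCT: two ellipsoidal lungs inside a soft-tissue
#' torso with a spine proxy, a diaphragm that rises sinusoidally from
#' end-inspiration (T00) to end-expiration (T50) and descends back by the
#' last phase, correlated parenchymal texture, and i.i.d. voxel noise.
#'
#' @param grid_shape voxels per axis (x, y, z); all entries must be >= 16.
#' @param spacing mm per voxel along (x, y, z).
#' @param n_phases number of breathing phases (>= 2); labels are assigned as
#'   `T00, T10, ...` by evenly dividing the cycle (10 phases give T00..T90).
#' @param diaphragm_amplitude peak diaphragm excursion across the cycle, in
#'   voxels (>= 1).
#' @param noise_sd standard deviation of the i.i.d. intensity noise, in HU.
#'   Must be positive: the noise is what makes non-interpolated adjacent
#'   axial slices distinguishable.
#' @param texture_scale spatial correlation length of the parenchymal
#'   texture, in voxels.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 32, 32), n_phases = 4)
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         n_phases = 10, diaphragm_amplitude = 8,
                         noise_sd = 20, texture_scale = 3, seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 16))
    stop("grid_shape must have 3 entries, all >= 16")
  if (n_phases < 2) stop("n_phases must be >= 2")
  if (diaphragm_amplitude < 1) stop("diaphragm_amplitude must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 n_phases = as.integer(n_phases),
                 diaphragm_amplitude = diaphragm_amplitude,
                 noise_sd = noise_sd, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phase_labels <- function(n_phases) {
  sprintf("T%02d", round(100 * (seq_len(n_phases) - 1) / n_phases))
}

# Diaphragm displacement (voxels) for phase index i (1-based): smooth
# symmetric cycle, 0 at T00, maximal (= amplitude) at mid-cycle.
diaphragm_displacement <- function(i, n_phases, amplitude) {
  amplitude * (1 - cos(2 * pi * (i - 1) / n_phases)) / 2
}

# Tissue intensities (HU) of the phantom.
PHANTOM_HU <- list(air = -1000, lung = -800, tissue = 40, spine = 500)

#' Noise-free phantom anatomy for one phase
#'
#' Builds the clean (noise- and texture-free) intensity grid and the paired
#' left/right lung mask for one breathing phase. Exposed mainly so that
#' intensity-ordering checks can be run on the noise-free intermediate.
#'
#' @param spec a [phantom_spec()].
#' @param phase_index 1-based phase index in `1..n_phases`.
#' @return list with `clean` (HU 3D array) and `mask` (0/1/2 integer array).
#' @export
phantom_anatomy <- function(spec, phase_index) {
  d <- spec$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  x <- seq_len(nx); y <- seq_len(ny); z <- seq_len(nz)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  X <- array(rep(x, times = ny * nz), d)
  Y <- array(rep(rep(y, each = nx), times = nz), d)
  Z <- array(rep(z, each = nx * ny), d)

  img <- array(PHANTOM_HU$air, d)
  torso <- ((X - cx) / (0.47 * nx))^2 + ((Y - cy) / (0.43 * ny))^2 <= 1
  img[torso] <- PHANTOM_HU$tissue
  spine <- ((X - cx) / (0.07 * nx))^2 + ((Y - (cy + 0.30 * ny)) / (0.07 * ny))^2 <= 1
  img[spine & torso] <- PHANTOM_HU$spine

  disp <- diaphragm_displacement(phase_index, spec$n_phases,
                                 spec$diaphragm_amplitude)
  cz <- 0.55 * nz
  rx <- 0.14 * nx; ry <- 0.23 * ny; rz <- 0.38 * nz
  mask <- array(0L, d)
  for (side in 1:2) {
    lcx <- cx + c(-1, 1)[side] * 0.20 * nx
    lcy <- cy - 0.05 * ny
    ell <- ((X - lcx) / rx)^2 + ((Y - lcy) / ry)^2 + ((Z - cz) / rz)^2 <= 1
    # The diaphragm (inferior lung boundary, low z) rises by `disp`; a gentle
    # in-plane tilt makes the cut sub-voxel so lung volume varies strictly
    # with the displacement.
    zfloor <- (cz - rz) + disp + (X - (lcx - rx)) / (2 * rx + 1e-9)
    lung <- ell & (Z >= zfloor)
    mask[lung] <- side
    img[lung] <- PHANTOM_HU$lung
  }
  list(clean = img, mask = mask)
}

#' Generate a synthetic multi-phase breathing series
#'
#' Produces `n_phases` co-registered volumes (HU domain) with paired binary
#' left/right lung masks. The lung masks follow the diaphragm exactly; lung
#' volume is maximal at T00 (end-inspiration) and minimal at mid-cycle
#' (end-expiration). A single correlated texture field (Gaussian-filtered
#' white noise at 20% of `noise_sd`) is shared by all phases, and i.i.d.
#' Gaussian noise is drawn independently per phase. Deterministic given the
#' spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phase_series`: list with `phases` (a list of
#'   `list(label, volume, mask)` in phase order) and `spec`.
#' @examples
#' s <- generate_phase_series(phantom_spec(grid_shape = c(24, 24, 24),
#'                                         n_phases = 2, seed = 7))
#' names(s$phases)
#' @export
generate_phase_series <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  labels <- phase_labels(spec$n_phases)
  with_seed(spec$seed, {
    texture <- gauss_smooth_3d(array(stats::rnorm(prod(spec$grid_shape)),
                                     spec$grid_shape),
                               spec$texture_scale) * (0.2 * spec$noise_sd)
    phases <- vector("list", spec$n_phases)
    for (i in seq_len(spec$n_phases)) {
      an <- phantom_anatomy(spec, i)
      noisy <- an$clean + texture +
        array(stats::rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
              spec$grid_shape)
      phases[[i]] <- list(label = labels[i],
                          volume = ct_volume(noisy, spec$spacing,
                                             phase = labels[i], domain = "HU"),
                          mask = lung_mask(an$mask, spec$spacing))
    }
    names(phases) <- labels
    structure(list(phases = phases, spec = spec), class = "phase_series")
  })
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d phases (%s), grid %s\n",
              length(x$phases),
              paste(names(x$phases), collapse = " "),
              paste(x$spec$grid_shape, collapse = "x")))
  invisible(x)
}

#' Per-phase summary of a phantom series
#'
#' @param series a [generate_phase_series()] result.
#' @return data.frame with one row per phase: `phase`, `lung_voxels`,
#'   `lung_volume_ml` (voxel count times voxel volume), `intensity_min`,
#'   `intensity_max`, `n_slices`, and `degenerate` (TRUE for an empty mask).
#' @export
phantom_summary <- function(series) {
  if (!inherits(series, "phase_series")) stop("`series` must be a phase_series")
  voxel_ml <- prod(series$spec$spacing) / 1000
  rows <- lapply(series$phases, function(p) {
    nv <- sum(p$mask$data > 0)
    data.frame(phase = p$label, lung_voxels = nv,
               lung_volume_ml = nv * voxel_ml,
               intensity_min = min(p$volume$data),
               intensity_max = max(p$volume$data),
               n_slices = dim(p$volume$data)[3],
               degenerate = nv == 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
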