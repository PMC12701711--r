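# Shared fixtures: small phantoms and labeled interpolation cases, all
# generated in code at test time.

small_series <- function(seed = 1, grid = c(32, 32, 32), n_phases = 10,
                         noise_sd = 20, amplitude = 6) {
  generate_phase_series(phantom_spec(grid_shape = grid, n_phases = n_phases,
                                     noise_sd = noise_sd,
                                     diaphragm_amplitude = amplitude,
                                     seed = seed))
}

# normalized T00/T50 pair from a fresh series
norm_pair <- function(seed = 1, grid = c(32, 32, 32), noise_sd = 20) {
  s <- small_series(seed, grid, noise_sd = noise_sd)
  list(primary = truncate_and_normalize(s$phases$T00$volume),
       secondary = truncate_and_normalize(s$phases$T50$volume),
       lung = s$phases$T00$mask, series = s)
}

# a labeled interpolation case on a noisy phantom
make_interp_case <- function(seed, grid = c(32, 32, 40), noise_sd = 20,
                             h = 6, n_intervals = 2, sigma_g = 1) {
  s <- generate_phase_series(phantom_spec(grid_shape = grid, n_phases = 2,
                                          noise_sd = noise_sd, seed = seed))
  v <- truncate_and_normalize(s$phases$T00$volume)
  ivs <- perturb_intervals(interp_params(h = h, n_intervals = n_intervals,
                                         sigma_g = sigma_g, seed = seed),
                           dim(v$data)[3])
  ir <- infuse_interpolation(v, ivs)
  list(volume = ir$volume, mask = ir$mask, intervals = ivs)
}

eps_profile <- function(p = 1e-3, n = 10) threshold_profile(rep(p, n))

# slice-level truth flags of a case
truth_slices <- function(case) apply(case$mask$data == 2L, 3, any)

# independent point-in-convex-hull oracle: q is in the hull iff it lies in
# some tetrahedron of 4 mask points (Caratheodory in 3D)
oracle_hull_membership <- function(queries, pts) {
  combs <- utils::combn(nrow(pts), 4)
  inside <- rep(FALSE, nrow(queries))
  for (j in seq_len(ncol(combs))) {
    if (all(inside)) break
    P <- pts[combs[, j], ]
    A <- t(P[2:4, ]) - P[1, ]
    if (abs(det(A)) < 1e-9) next
    w <- solve(A, t(queries) - P[1, ])
    inside <- inside | (colSums(w < -1e-9) == 0 & colSums(w) <= 1 + 1e-9)
  }
  inside
}

# digital ball mask of radius r (1 mm spacing)
digital_ball <- function(r, pad = 3) {
  n <- 2 * r + 2 * pad + 1
  c0 <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2, c(n, n, n))
}
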