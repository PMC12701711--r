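# Internal helpers: seeded RNG scoping, separable Gaussian smoothing,
# bounding boxes.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stage label (stable, < 2^31).
derive_seed <- function(seed, label, i = 0L) {
  s <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 48271 + s * 7919 + i * 104729) %% 2147483629
}

gauss_kernel_1d <- function(sigma) {
  if (sigma < 1e-8) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along index with edge replication.
convolve_replicate <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(x * k)
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + length(x))]
}

# Separable Gaussian smoothing of a 3D array (replicated edges).
gauss_smooth_3d <- function(a, sigma) {
  if (sigma < 1e-8) return(a)
  k <- gauss_kernel_1d(sigma)
  d <- dim(a)
  # along x: treat as d1 x (d2*d3) matrix
  m <- matrix(a, d[1], d[2] * d[3])
  m <- apply(m, 2, convolve_replicate, k = k)
  a <- array(m, d)
  # along y
  a <- aperm(a, c(2, 1, 3))
  m <- matrix(a, d[2], d[1] * d[3])
  m <- apply(m, 2, convolve_replicate, k = k)
  a <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # along z
  a <- aperm(a, c(3, 2, 1))
  m <- matrix(a, d[3], d[2] * d[1])
  m <- apply(m, 2, convolve_replicate, k = k)
  aperm(array(m, c(d[3], d[2], d[1])), c(3, 2, 1))
}

# Tight bounding box (1-based, inclusive) of nonzero voxels of a 3D array.
# Returns list(lo = c(x,y,z), hi = c(x,y,z)) or NULL for an empty mask.
bbox_of <- function(a) {
  idx <- which(a != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

expand_bbox <- function(bb, margin, dims) {
  list(lo = pmax(bb$lo - margin, 1L), hi = pmin(bb$hi + margin, dims))
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}
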