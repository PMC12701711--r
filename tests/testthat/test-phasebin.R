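test_that("stacks are placed in the inferior lung half with the right mass", {
  pair <- norm_pair(seed = 1)
  nz <- dim(pair$primary$data)[3]
  zr <- range(which(apply(pair$lung$data > 0, 3, any)))
  zmid <- floor(mean(zr))
  for (i in 1:25) {
    sm <- build_stack_mask(nz, pb_params(h = 4, n_stacks = 2, seed = i),
                           pair$lung)
    expect_equal(sum(sm$binary_profile), 8)            # n_stacks * h slices
    on <- which(sm$binary_profile > 0)
    expect_true(all(on >= zr[1] & on <= zmid))         # inferior half only
  }
  sm1 <- build_stack_mask(nz, pb_params(h = 4, n_stacks = 2, seed = 7), pair$lung)
  sm2 <- build_stack_mask(nz, pb_params(h = 4, n_stacks = 2, seed = 7), pair$lung)
  expect_identical(sm1, sm2)
  expect_error(build_stack_mask(nz, pb_params(h = 200, n_stacks = 1), pair$lung),
               "fit")
})

test_that("feathering stays in [0,1], widens with sigma, and vanishes as sigma -> 0", {
  pair <- norm_pair(seed = 2)
  nz <- dim(pair$primary$data)[3]
  sm <- build_stack_mask(nz, pb_params(h = 4, n_stacks = 1, seed = 3), pair$lung)
  f0 <- feather_stack_mask(sm, 1e-9)
  expect_equal(f0$feathered_profile, sm$binary_profile)
  f1 <- feather_stack_mask(sm, 1)
  f3 <- feather_stack_mask(sm, 3)
  for (f in list(f1, f3)) {
    expect_true(all(f$feathered_profile >= 0 & f$feathered_profile <= 1))
    expect_equal(max(f$feathered_profile), 1)  # renormalized peak
  }
  expect_gt(sum(f3$feathered_profile > 0.05), sum(f1$feathered_profile > 0.05))
})

test_that("secondary shift is local to stacks and matches direct index arithmetic", {
  pair <- norm_pair(seed = 3)
  nz <- dim(pair$primary$data)[3]
  sm <- build_stack_mask(nz, pb_params(h = 4, n_stacks = 1, seed = 5), pair$lung)
  expect_identical(shift_secondary(pair$secondary, sm, 0, seed = 1)$data,
                   pair$secondary$data)
  sh <- shift_secondary(pair$secondary, sm, 2, seed = 9)
  outside <- sm$binary_profile == 0
  expect_identical(sh$data[, , outside], pair$secondary$data[, , outside])
  # on a linear in-plane ramp the shifted stack equals the translated ramp
  d <- dim(pair$primary$data)
  ramp <- ct_volume(array(rep(seq(0, 1, length.out = d[1]), times = d[2] * d[3]), d),
                    domain = "normalized")
  shr <- shift_secondary(ramp, sm, 1, seed = 11)
  z0 <- which(sm$binary_profile > 0)[1]
  sl <- shr$data[, , z0]
  # recover the drawn x-offset from the interior and check the translation
  off <- round((ramp$data[10, 1, z0] - sl[10, 1]) * (d[1] - 1))
  expect_true(off %in% -1:1)
  interior <- (1 + max(0, off)):(d[1] + min(0, off))
  expect_equal(sl[interior, 5], ramp$data[interior - off, 5, z0], tolerance = 1e-12)
  expect_error(shift_secondary(pair$secondary, sm, -1), ">= 0")
})

test_that("admissibility counts match the stated examples and a voxel-loop oracle", {
  d <- c(4, 4, 4)
  sm <- list(feathered_profile = rep(1, 4),
             stacks = data.frame(z_start = 1, height = 4))
  I <- array(0.5, d); Ig <- array(0.8, d)
  expect_true(check_admissibility(I, Ig, sm)$admissible)   # I - Ig all negative
  same <- check_admissibility(I, I, sm)
  expect_false(same$admissible)                            # C = 0: counts tie
  expect_equal(same$n_nonpositive, same$n_nonnegative)
  # direct count with a zero on both sides: {-1,-1,0,1} -> 3 > 2
  I2 <- array(0, c(1, 1, 4)); Ig2 <- array(0, c(1, 1, 4))
  I2[1, 1, ] <- c(0, 0, 0.5, 1); Ig2[1, 1, ] <- c(1, 1, 0.5, 0)
  sm2 <- list(feathered_profile = rep(1, 4),
              stacks = data.frame(z_start = 1, height = 4))
  chk <- check_admissibility(I2, Ig2, sm2)
  expect_equal(chk$n_nonpositive, 3)
  expect_equal(chk$n_nonnegative, 2)
  expect_true(chk$admissible)
  # brute-force voxel loop on a random 12^3 grid
  set.seed(8)
  d <- c(12, 12, 12)
  I <- array(runif(prod(d)), d); Ig <- array(runif(prod(d)), d)
  w <- runif(12)
  smw <- list(feathered_profile = w, stacks = data.frame(z_start = 1, height = 12))
  got <- check_admissibility(I, Ig, smw)
  npos <- 0L; nneg <- 0L
  for (x in 1:12) for (y in 1:12) for (z in 1:12) {
    cv <- w[z] * (I[x, y, z] - Ig[x, y, z])
    if (cv <= 0) nneg <- nneg + 1L
    if (cv >= 0) npos <- npos + 1L
  }
  expect_equal(got$n_nonpositive, nneg)
  expect_equal(got$n_nonnegative, npos)
  expect_equal(got$admissible, nneg > npos)
})

test_that("blending is the per-slice convex combination of the two phases", {
  d <- c(6, 6, 5)
  set.seed(3)
  I <- array(runif(prod(d)), d); Ig <- array(runif(prod(d)), d)
  smz <- list(feathered_profile = rep(0, 5), stacks = data.frame())
  expect_identical(blend_stack(I, Ig, smz), I)
  smo <- list(feathered_profile = c(0, 1, 0, 0, 0), stacks = data.frame())
  out <- blend_stack(I, Ig, smo)
  expect_identical(out[, , 2], Ig[, , 2])
  expect_identical(out[, , -2], I[, , -2])
  smh <- list(feathered_profile = rep(0.5, 5), stacks = data.frame())
  I2 <- array(0.2, d); Ig2 <- array(0.6, d)
  expect_equal(unique(as.vector(blend_stack(I2, Ig2, smh))), 0.4)
  # convexity: always between the two inputs
  outh <- blend_stack(I, Ig, smh)
  expect_true(all(outh >= pmin(I, Ig) - 1e-12 & outh <= pmax(I, Ig) + 1e-12))
})

test_that("ground-truth mask derivation thresholds, closes and filters components", {
  d <- c(24, 24, 24)
  I <- array(0.2, d)
  params <- pb_params(h = 4, sigma_g = 1, lambda0 = 0.1, min_component = 50)
  expect_equal(sum(derive_pb_mask(I, I, params)$data), 0)   # no difference
  # a solid block above threshold survives closing and filtering
  Ihat <- I; Ihat[5:14, 5:14, 5:10] <- 0.7
  m <- derive_pb_mask(I, Ihat, params)
  expect_equal(sum(m$data == 1L), 10 * 10 * 6)
  expect_true(all(m$data[5:14, 5:14, 5:10] == 1L))
  # isolated speckle voxels are removed by the component filter
  Isp <- I
  for (p in list(c(3, 3, 3), c(12, 18, 7), c(20, 4, 15)))
    Isp[p[1], p[2], p[3]] <- 0.9
  expect_equal(sum(derive_pb_mask(I, Isp, params)$data), 0)
  expect_error(derive_pb_mask(I, I, pb_params(sigma_g = 25, lambda0 = 0.05)),
               "lambda")
})

test_that("full infusion accepts opposite-phase pairs, rejects self-pairing, and stays local", {
  pair <- norm_pair(seed = 6)
  # without an in-plane shift, self-pairing gives C = 0 and a tied count:
  # never admissible, whatever the placement draws
  params0 <- pb_params(h = 5, n_stacks = 1, sigma_g = 1, shift_intensity = 0,
                       seed = 21)
  self <- infuse_phase_binning(pair$primary, pair$primary, pair$lung, params0)
  expect_false(self$accepted)
  expect_equal(self$n_nonpositive, self$n_nonnegative)
  params <- pb_params(h = 5, n_stacks = 1, sigma_g = 1, seed = 21)
  res <- infuse_phase_binning(pair$primary, pair$secondary, pair$lung, params)
  expect_true(res$accepted)
  expect_gt(sum(res$mask$data == 1L), 0)
  support <- res$stack_mask$feathered_profile > 0
  mask_slices <- apply(res$mask$data == 1L, 3, any)
  expect_true(all(!mask_slices | support))         # artifacts only in stacks
  outside <- !support
  expect_identical(res$volume$data[, , outside], pair$primary$data[, , outside])
  # determinism of the whole pipeline
  res2 <- infuse_phase_binning(pair$primary, pair$secondary, pair$lung, params)
  expect_identical(res$volume$data, res2$volume$data)
  expect_identical(res$mask$data, res2$mask$data)
})
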