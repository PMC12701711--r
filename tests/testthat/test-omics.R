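test_that("a solid box fills its bounding box and convex hull exactly", {
  b <- array(0L, c(16, 10, 8)); b[4:13, 3:6, 3:4] <- 1L
  f <- extract_artifact_features(artifact_mask(b), min_volume = 10)
  expect_equal(nrow(f), 1)
  expect_equal(f$volume, 80)
  expect_equal(f$bbox_volume, 80)
  expect_equal(f$extent, 1)
  expect_equal(f$solidity, 1)
  expect_equal(f$equivalent_diameter, (6 * 80 / pi)^(1 / 3))
})

test_that("a digital ball is nearly spherical with unit elongations", {
  ball <- digital_ball(12)
  f <- extract_artifact_features(artifact_mask(array(as.integer(ball), dim(ball))))
  expect_lt(abs(f$sphericity - 1), 0.1)
  expect_lt(f$elongation_major_minor, 1.1)
  expect_gt(f$flatness, 0.9)
  expect_gt(f$solidity, 0.9)
})

test_that("axis lengths are ordered and elongations at least one on random components", {
  set.seed(31)
  for (rep in 1:5) {
    # random ellipsoid blob with voxels knocked out: connected, irregular
    d <- c(14, 14, 14)
    g <- expand.grid(x = 1:14, y = 1:14, z = 1:14)
    ax <- runif(3, 2.5, 5)
    b <- array(((g$x - 7.5) / ax[1])^2 + ((g$y - 7.5) / ax[2])^2 +
                 ((g$z - 7.5) / ax[3])^2 <= 1, d)
    b[b & runif(prod(d)) < 0.15] <- FALSE
    f <- extract_artifact_features(artifact_mask(array(as.integer(b), d)),
                                   min_volume = 20)
    expect_gte(nrow(f), 1)
    f <- f[which.max(f$volume), ]
    expect_gte(f$major_axis_length, f$intermediate_axis_length)
    expect_gte(f$intermediate_axis_length, f$minor_axis_length)
    expect_gte(f$elongation_major_minor, 1)
    expect_gte(f$elongation_major_intermediate, 1)
    expect_gte(f$elongation_intermediate_minor, 1)
    expect_lte(f$solidity, 1)
    expect_lte(f$extent, 1)
    expect_lte(f$volume, f$bbox_volume)
  }
})

test_that("solidity agrees with a brute-force tetrahedron-membership hull oracle", {
  set.seed(32)
  for (rep in 1:4) {
    b <- array(FALSE, c(9, 9, 9))
    idx <- unique(cbind(sample(2:8, 22, TRUE), sample(2:8, 22, TRUE),
                        sample(2:8, 22, TRUE)))
    b[idx] <- TRUE
    ci <- artifactlab:::convex_image(b)
    g <- as.matrix(expand.grid(1:9, 1:9, 1:9))
    expect_equal(ci[g], oracle_hull_membership(g, idx))
  }
})

test_that("identical groups come out equivalent, separated groups different", {
  set.seed(33)
  # TOST at +-0.2 pooled SDs needs samples large enough that the standard
  # error of the mean difference is well below the bound
  fa <- data.frame(volume = rnorm(1000, 100, 10), solidity = runif(1000, 0.7, 0.9))
  fb <- data.frame(volume = rnorm(1000, 100, 10), solidity = runif(1000, 0.7, 0.9))
  cmp <- compare_feature_groups(fa, fb)
  expect_true(all(cmp$tost_q < 0.05))   # equivalence established
  expect_true(all(cmp$verdict %in% c("equivalent", "both")))
  fc <- data.frame(volume = rnorm(200, 130, 10), solidity = runif(200, 0.2, 0.4))
  cmp2 <- compare_feature_groups(fa, fc)
  expect_true(all(cmp2$verdict == "different"))
  # tiny noisy groups resolve nothing
  fd <- data.frame(volume = c(10, 200, 80), solidity = c(0.1, 0.9, 0.5))
  fe <- data.frame(volume = c(150, 20, 90), solidity = c(0.8, 0.2, 0.4))
  cmp3 <- compare_feature_groups(fd, fe)
  expect_true(all(cmp3$verdict == "inconclusive"))
})

test_that("verdicts are invariant to affine rescaling of raw features", {
  set.seed(34)
  fa <- data.frame(volume = rnorm(80, 100, 10))
  fb <- data.frame(volume = rnorm(80, 104, 10))
  v1 <- compare_feature_groups(fa, fb)$verdict
  v2 <- compare_feature_groups(transform(fa, volume = 1000 * volume + 5),
                               transform(fb, volume = 1000 * volume + 5))$verdict
  expect_identical(v1, v2)
  expect_warning(compare_feature_groups(data.frame(volume = rep(1, 5)),
                                        data.frame(volume = rep(1, 5))),
                 "constant")
})

test_that("Spearman correlation hits its extremes and vanishes under independence", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(paired_spearman(x, x)$rho, 1)
  expect_equal(paired_spearman(x, -x)$rho, -1)
  set.seed(35)
  nullr <- paired_spearman(rnorm(1000), rnorm(1000))
  expect_lt(abs(nullr$rho), 0.1)
  expect_error(paired_spearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(paired_spearman(1:3, 1:3), "length")
})
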