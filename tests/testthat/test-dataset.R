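test_that("the default combination table yields exactly seven (h, NPB) pairs", {
  combos <- enumerate_combinations(combination_spec())
  expect_equal(nrow(combos), 7)
  expect_equal(combos$h, c(4, 4, 4, 4, 8, 8, 16))
  expect_equal(combos$npb, c(1, 2, 3, 4, 1, 2, 1))
  one <- enumerate_combinations(combination_spec(data.frame(h = 16, npb_max = 1,
                                                            nint_max = 2)))
  expect_equal(nrow(one), 1)
  two <- enumerate_combinations(combination_spec(data.frame(h = c(4, 8),
                                                            npb_max = c(2, 2),
                                                            nint_max = c(1, 1))))
  expect_equal(nrow(two), 4)
})

test_that("secondary-phase pairing follows the opposite / neighbourhood / random criteria", {
  expect_equal(choose_secondary_phase("T30", "opposite"), "T80")
  expect_equal(choose_secondary_phase("T00", "opposite"), "T50")
  nbhd <- unique(vapply(1:200, function(s)
    choose_secondary_phase("T30", "opposite_nbhd", seed = s), character(1)))
  expect_setequal(nbhd, c("T60", "T70", "T80", "T90", "T00"))
  rnd <- vapply(1:200, function(s)
    choose_secondary_phase("T00", "random", seed = s), character(1))
  expect_false("T00" %in% rnd)
  expect_gt(length(unique(rnd)), 5)
  expect_error(choose_secondary_phase("T95", "opposite"), "unknown")
})

test_that("template splits follow the 0.85/0.15 partitions with round-half-up", {
  sp <- split_templates(100, seed = 1)
  expect_length(sp$untouched, 15)
  expect_length(sp$train_templates, 72)
  expect_length(sp$test_templates, 13)
  expect_equal(sort(c(sp$train_templates, sp$test_templates, sp$untouched)),
               1:100)
  # the published cohort sizes are reproduced within rounding slack
  sp2 <- split_templates(1074, seed = 2)
  expect_lte(abs(length(sp2$train_templates) - 775), 2)
  expect_lte(abs(length(sp2$test_templates) - 138), 2)
  expect_lte(abs(length(sp2$untouched) - 161), 2)
  expect_identical(split_templates(50, seed = 9), split_templates(50, seed = 9))
})

test_that("the oversampling schedule starts at the initial rate and decays to the target", {
  s <- oversampling_rate(5)
  expect_equal(s, 0.8)
  expect_equal(oversampling_rate(0), 0.8)      # before decay starts
  expect_equal(oversampling_rate(1e6), 0.4, tolerance = 1e-12)
  expect_equal(oversampling_rate(10, r_initial = 0.5, r_target = 0.5), 0.5)
  e <- 5:50
  r <- oversampling_rate(e)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 0.4 & r <= 0.8))
  expect_error(oversampling_rate(5, decay_k = 0), "decay_k")
})

test_that("dataset assembly respects case-count bounds, negative purity and summary re-aggregation", {
  series_list <- lapply(1:4, function(i)
    small_series(seed = 200 + i, grid = c(28, 28, 28), n_phases = 10))
  comb <- combination_spec(data.frame(h = 4, npb_max = 1, nint_max = 2))
  cfg <- build_config(pairing = "opposite", nc_train = 1, nc_test = 1,
                      p_zero_interp = 0.3, seed = 7)
  ds <- build_dataset(series_list, cfg, comb)
  sp <- ds$splits
  n_train_max <- length(sp$train_templates) * 1 * 1
  expect_lte(sum(ds$cases$split == "train"), n_train_max)
  expect_gte(nrow(ds$cases), length(sp$untouched))
  # untouched negatives carry empty artifact masks
  for (i in which(ds$cases$split == "untouched"))
    expect_equal(sum(ds$volumes[[i]]$mask$data), 0)
  # manifest statistics agree with brute-force re-aggregation over the masks
  for (i in which(ds$cases$split == "train")) {
    m <- ds$volumes[[i]]$mask$data
    expect_equal(ds$cases$pb_voxels[i], sum(m == 1L))
    expect_equal(ds$cases$int_voxels[i], sum(m == 2L))
    expect_equal(ds$cases$pb_slices[i], sum(apply(m == 1L, 3, any)))
  }
  tr <- ds$cases[ds$cases$split == "train", ]
  if (nrow(tr) > 1) {
    expect_equal(ds$summary[ds$summary$split == "train", "pb_volume_pct"],
                 mean(tr$pb_volume_pct))
  }
  # labels never overlap: a voxel is phase-binning or interpolation, not both
  for (cs in ds$volumes) expect_true(all(cs$mask$data %in% c(0L, 1L, 2L)))
})

test_that("dataset build is reproducible bit-for-bit from the same seeds", {
  series_list <- lapply(1:3, function(i)
    small_series(seed = 230 + i, grid = c(24, 24, 24), n_phases = 10))
  comb <- combination_spec(data.frame(h = 4, npb_max = 1, nint_max = 1))
  cfg <- build_config(pairing = "random", nc_train = 1, nc_test = 1, seed = 3)
  ds1 <- build_dataset(series_list, cfg, comb)
  ds2 <- build_dataset(series_list, cfg, comb)
  expect_identical(ds1$cases, ds2$cases)
  for (i in seq_along(ds1$volumes))
    expect_identical(ds1$volumes[[i]]$volume$data, ds2$volumes[[i]]$volume$data)
})
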