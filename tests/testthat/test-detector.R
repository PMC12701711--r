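test_that("slice-to-segment mapping divides the axial axis into equal deciles", {
  expect_equal(segment_of(1, 100, 10), 1)
  expect_equal(segment_of(6, 100, 10), 1)     # first decile
  expect_equal(segment_of(96, 100, 10), 10)   # last decile
  expect_equal(segment_of(51, 100, 10), 6)    # boundary falls upward
  expect_equal(segment_of(50, 100, 10), 5)
  expect_error(segment_of(0, 100, 10), "range")
  # every slice lands in exactly one segment, and counts are equal
  segs <- segment_of(1:100, 100, 10)
  expect_equal(as.vector(table(segs)), rep(10, 10))
})

test_that("the scan tests every sliding interval of the requested lengths", {
  set.seed(12)
  x <- array(runif(3 * 3 * 10), c(3, 3, 10))
  tab <- artifactlab:::interval_diff_table(x, c(3, 4), 10)
  expect_equal(nrow(tab), 8 + 7)
  # thresholds of 1 keep everything, 0 keeps nothing
  expect_equal(nrow(scan_intervals(x, threshold_profile(rep(0.999, 10)))), 15)
  expect_equal(nrow(scan_intervals(x, threshold_profile(rep(1e-9, 10)))), 0)
})

test_that("candidate sets grow monotonically with the threshold", {
  case <- make_interp_case(seed = 13)
  c1 <- scan_intervals(case$volume, eps_profile(0.01))
  c2 <- scan_intervals(case$volume, eps_profile(0.05))
  key <- function(d) paste(d$z_start, d$z_end)
  expect_true(all(key(c1) %in% key(c2)))
})

test_that("consolidation merges, drops contained intervals, and is idempotent", {
  cand <- data.frame(z_start = c(2, 3), z_end = c(4, 5))
  out <- consolidate(cand)
  expect_equal(out, data.frame(z_start = 2L, z_end = 5L))
  cand2 <- data.frame(z_start = c(2, 2), z_end = c(4, 5))
  expect_equal(consolidate(cand2), data.frame(z_start = 2L, z_end = 5L))
  cand3 <- data.frame(z_start = c(2, 8), z_end = c(4, 10))
  expect_equal(consolidate(cand3),
               data.frame(z_start = c(2L, 8L), z_end = c(4L, 10L)))
  # abutting intervals reunite into the full artifact interval
  cand4 <- data.frame(z_start = c(2, 5), z_end = c(4, 7))
  expect_equal(consolidate(cand4), data.frame(z_start = 2L, z_end = 7L))
  once <- consolidate(cand)
  expect_equal(consolidate(once), once)
})

test_that("epsilon thresholds recover infused intervals exactly; clean volumes yield none", {
  case <- make_interp_case(seed = 14, n_intervals = 2)
  det <- detect_interpolation(case$volume, eps_profile())
  truth <- truth_slices(case)
  expect_identical(det$slice_flags, truth)
  got <- det$intervals
  want <- do.call(rbind, lapply(case$intervals, function(iv)
    data.frame(z_start = iv$z_start, z_end = iv$z_end)))
  expect_equal(got, want)
  clean <- truncate_and_normalize(
    small_series(seed = 15, n_phases = 2)$phases$T00$volume)
  det0 <- detect_interpolation(clean, eps_profile())
  expect_equal(nrow(det0$intervals), 0)
  expect_false(any(det0$slice_flags))
})

test_that("detection is independent of segment evaluation order", {
  case <- make_interp_case(seed = 16)
  prof <- eps_profile(0.05)
  full <- scan_intervals(case$volume, prof)
  per_segment <- do.call(rbind, lapply(sample(1:10), function(s)
    full[full$segment == s, , drop = FALSE]))
  expect_identical(consolidate(per_segment), consolidate(full))
})

test_that("segment Dice responds to the threshold as the overlap dictates", {
  case <- make_interp_case(seed = 17, n_intervals = 1)
  nz <- dim(case$volume$data)[3]
  truth <- truth_slices(case)
  seg <- segment_of(floor(mean(which(truth))), nz, 10)
  # epsilon threshold: perfect in that segment
  expect_equal(dice_for_threshold(list(case), seg, 1e-3), 1)
  # threshold far above the noise floor floods the segment with positives
  d_hi <- dice_for_threshold(list(case), seg, 0.9)
  expect_lt(d_hi, 1)
  expect_warning(dice_for_threshold(list(case), segment_of(1, nz, 10), 1e-3),
                 "no ground-truth")
})

test_that("fitted thresholds respect the bounds, are deterministic, and both solvers attain zero loss", {
  cases <- lapply(1:4, function(i)
    make_interp_case(seed = 300 + i, grid = c(40, 40, 40), noise_sd = 200))
  fit1 <- suppressMessages(fit_interp_detector(cases, n_folds = 4, seed = 5))
  fit2 <- suppressMessages(fit_interp_detector(cases, n_folds = 4, seed = 5))
  expect_identical(coef(fit1), coef(fit2))
  expect_true(all(coef(fit1) > fit1$bounds[1] & coef(fit1) < fit1$bounds[2]))
  expect_true(all(fit1$cv$held_out_dice == 1))
  fitb <- suppressMessages(fit_interp_detector(cases, method = "brent",
                                               n_folds = 2, seed = 5))
  for (fit in list(fit1, fitb)) {
    d <- vapply(cases, function(cs) {
      det <- predict(fit, cs$volume)
      artifactlab:::dice_binary(det$slice_flags, truth_slices(cs))
    }, numeric(1))
    expect_equal(d, rep(1, length(cases)))
  }
})

test_that("the detector object behaves like a fitted model", {
  cases <- lapply(1:2, function(i)
    make_interp_case(seed = 320 + i, grid = c(32, 32, 32), noise_sd = 200))
  fit <- suppressMessages(fit_interp_detector(cases, n_folds = 2, seed = 1))
  expect_s3_class(fit, "interp_detector")
  expect_length(coef(fit), 10)
  expect_output(print(fit), "thresholds")
  expect_output(summary(fit), "held-out|CV")
  det <- predict(fit, cases[[1]]$volume)
  expect_s3_class(det, "interp_detection")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
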