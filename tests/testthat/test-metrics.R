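test_that("Dice handles perfect, disjoint, empty and mixed overlaps", {
  a <- array(c(1, 1, 0, 0), c(2, 2, 1))
  expect_equal(dice_score(a, a), 1)
  b <- array(c(0, 0, 1, 1), c(2, 2, 1))
  expect_equal(dice_score(a, b), 0)
  e <- array(0, c(2, 2, 1))
  expect_equal(dice_score(e, e), 1)           # both empty by convention
  # TP=2, FP=1, FN=1 -> 4/6
  p <- array(c(1, 1, 1, 0), c(2, 2, 1))
  t <- array(c(1, 1, 0, 1), c(2, 2, 1))
  expect_equal(dice_score(p, t), 2 / 3)
  expect_equal(dice_score(p, t), dice_score(t, p))   # symmetric
  expect_error(dice_score(a, array(0, c(3, 3, 1))), "shape")
})

test_that("slice, stack and region inference matches constructed cases", {
  d <- c(6, 6, 20)
  t <- array(0L, d); t[2:4, 2:4, 10:13] <- 1L
  p <- array(0L, d); p[2:4, 2:4, 11:13] <- 1L
  cs <- confusion_counts(p, t, "slice")
  expect_equal(cs$tp, 3); expect_equal(cs$fn, 1); expect_equal(cs$fp, 0)
  # identity prediction is perfect on every level
  for (lv in c("voxel", "slice", "stack", "region")) {
    cc <- confusion_counts(t, t, lv)
    expect_equal(cc$fp, 0)
    expect_equal(cc$fn, 0)
    expect_gt(cc$tp, 0)
  }
  # two fully-predicted truth components: region TP=2, FP=0
  t2 <- array(0L, d)
  t2[2:3, 2:3, 3:5] <- 1L; t2[4:5, 4:5, 15:17] <- 1L
  cr <- confusion_counts(t2, t2, "region")
  expect_equal(cr$tp, 2); expect_equal(cr$fp, 0); expect_equal(cr$fn, 0)
  # a prediction overlapping no truth box is a region FP
  p3 <- array(0L, d); p3[1:2, 1:2, 1:2] <- 1L
  cr2 <- confusion_counts(p3, t2, "region")
  expect_equal(cr2$fp, 1); expect_equal(cr2$fn, 2)
  # stack-level: >= 50% slice coverage makes a TP
  phalf <- array(0L, d); phalf[2:4, 2:4, 10:11] <- 1L
  ck <- confusion_counts(phalf, t, "stack")
  expect_equal(ck$tp, 1)
  pq <- array(0L, d); pq[2:4, 2:4, 10] <- 1L
  ck2 <- confusion_counts(pq, t, "stack", stack_tp_frac = 0.5)
  expect_equal(ck2$tp, 0); expect_equal(ck2$fn, 1)
})

test_that("voxel and slice inference agree with a brute-force reimplementation", {
  set.seed(21)
  for (rep in 1:5) {
    d <- c(8, 8, 16)
    p <- array(runif(prod(d)) < 0.1, d)
    t <- array(runif(prod(d)) < 0.1, d)
    cv <- confusion_counts(p, t, "voxel")
    expect_equal(cv$tp, sum(p & t))
    expect_equal(cv$tn, sum(!p & !t))
    cs <- confusion_counts(p, t, "slice", min_voxels = 2)
    ps <- ts <- logical(16)
    for (z in 1:16) { ps[z] <- sum(p[, , z]) >= 2; ts[z] <- sum(t[, , z]) >= 2 }
    expect_equal(cs$tp, sum(ps & ts))
    expect_equal(cs$fp, sum(ps & !ts))
    expect_equal(cs$fn, sum(!ps & ts))
  }
})

test_that("weighted averages and Youden's J follow their definitions", {
  expect_equal(weighted_average(c(0.2, 0.9), c(1, 1)), 0.55)
  expect_equal(weighted_average(c(0.2, 0.9), c(1, 0)), 0.2)
  expect_equal(weighted_average(c(1, 0), c(3, 1)), 0.75)
  expect_error(weighted_average(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_average(1, c(1, 2)), "lengths")
  expect_equal(youden_j(1, 1), 1)
  expect_equal(youden_j(0.5, 0.5), 0)
  expect_equal(youden_j(0, 0), -1)
  expect_error(youden_j(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the overfitting index spans [0, 2] with the documented verdicts", {
  expect_equal(overfit_index(0.2, 0.2)$phi, 1)
  expect_equal(overfit_index(0.1, 0.3)$phi, 0.5)
  expect_equal(overfit_index(0.3, 0)$phi, 2)
  expect_equal(overfit_index(0.3, 0)$verdict, "generalizable")
  expect_equal(overfit_index(0.1, 0.3)$verdict, "over-fitting")
  expect_equal(overfit_index(0.28, 0.3)$verdict, "acceptable")
  expect_error(overfit_index(0, 0), "undefined")
  expect_error(overfit_index(1.5, 0.2), "\\[0, 1\\]")
  # scaling both losses leaves phi unchanged (ratio form)
  expect_equal(overfit_index(0.1, 0.25)$phi, overfit_index(0.2, 0.5)$phi)
})

test_that("boundary smoothness recovers the analytic sphere ratio and penalizes jagged masks", {
  expect_equal(heron_area(3, 4, 5), 6)
  expect_equal(heron_area(1, 1, 2), 0)      # degenerate triangle
  ball <- digital_ball(12)
  bs <- boundary_smoothness(ball)
  expect_lt(abs(bs$beta - 3 / 12) / (3 / 12), 0.1)
  expect_equal(bs$volume, sum(ball))
  # spacing scales area by s^2 and volume by s^3
  bs2 <- boundary_smoothness(ball, spacing = c(2, 2, 2))
  expect_equal(bs2$beta, bs$beta / 2, tolerance = 1e-9)
  # checkerboard-carved surface raises the surface-to-volume ratio
  jag <- ball
  idx <- which(ball, arr.ind = TRUE)
  surf <- idx[(idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0, , drop = FALSE]
  c0 <- (dim(ball)[1] + 1) / 2
  rr <- sqrt(rowSums((surf - c0)^2))
  jag[surf[rr > 10, , drop = FALSE]] <- FALSE
  bj <- boundary_smoothness(jag)
  expect_gt(bj$beta, bs$beta)
  expect_error(boundary_smoothness(array(FALSE, c(4, 4, 4))), "empty")
})
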