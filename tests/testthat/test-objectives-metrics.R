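test_that("cross-entropy matches hand-computed cases", {
  # near one-hot at the truth: ~0
  p <- array(c(1 - 1e-12, 1e-12), c(1, 1, 2))
  expect_lt(cross_entropy_loss(p, array(0L, c(1, 1))), 1e-10)
  # uniform over 4 classes: log 4
  pu <- array(0.25, c(3, 3, 4))
  yu <- array(sample(0:3, 9, TRUE), c(3, 3))
  expect_equal(cross_entropy_loss(pu, yu), log(4), tolerance = 1e-12)
  # two pixels with true-class probabilities 0.5 and 0.25
  p2 <- array(c(0.5, 0.25, 0.5, 0.75), c(2, 1, 2))
  y2 <- array(0L, c(2, 1))
  expect_equal(cross_entropy_loss(p2, y2), (log(2) + log(4)) / 2,
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(pu, array(7L, c(3, 3))), "label values")
})

test_that("soft Dice loss matches hand-computed cases", {
  # perfect hard prediction: ~0
  y <- array(c(0L, 1L, 1L, 0L), c(2, 2))
  p <- array(0, c(2, 2, 2))
  p[, , 1] <- (y == 0) * 1
  p[, , 2] <- (y == 1) * 1
  expect_lt(dice_loss(p, y), 1e-5)
  # fully disjoint hard prediction: ~1
  pd <- array(0, c(2, 2, 2))
  pd[, , 1] <- (y == 1) * 1
  pd[, , 2] <- (y == 0) * 1
  expect_gt(dice_loss(pd, y), 1 - 1e-4)
  # |X| = 4, |Y| = 4, overlap 2 on the foreground class: 1 - 2*2/8 = 0.5
  yy <- matrix(0L, 4, 4); yy[1:2, 1:2] <- 1L   # |Y| = 4
  pp <- array(0, c(4, 4, 2))
  pp[, , 2][2:3, 1:2] <- 1                      # |X| = 4, overlap 2
  pp[, , 1] <- 1 - pp[, , 2]
  expect_equal(dice_loss(pp, yy, classes = 1L), 0.5, tolerance = 1e-4)
})

test_that("total loss is the halved sum of its two terms", {
  set.seed(50)
  M <- 3L
  z <- array(rnorm(6 * 6 * M), c(6, 6, M))
  p <- exp(z); p <- p / array(rep(apply(p, c(1, 2), sum), M), dim(p))
  y <- array(sample(0:(M - 1), 36, TRUE), c(6, 6))
  expect_equal(total_loss(p, y),
               (cross_entropy_loss(p, y) + dice_loss(p, y)) / 2,
               tolerance = 1e-12)
  # complement identity: dice loss + mean soft Dice = 1
  expect_equal(dice_loss(p, y) + mean(soft_dice_per_class(p, y)), 1,
               tolerance = 1e-12)
})

test_that("Dice similarity coefficient handles the boundary conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dsc_metric(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dsc_metric(a, b), 0)
  c2 <- matrix(FALSE, 4, 4); c2[2:3, 1:2] <- TRUE  # overlap 2, 4 vs 4
  expect_equal(dsc_metric(a, c2), 0.5)
  none <- matrix(FALSE, 4, 4)
  expect_equal(dsc_metric(none, none), 1)  # both empty: perfect agreement
  expect_equal(dsc_metric(a, none), 0)     # single empty
  expect_error(dsc_metric(a, matrix(FALSE, 3, 3)), "shapes")
})

test_that("Hausdorff distance matches hand cases and rejects empty sets", {
  A <- cbind(c(1, 2, 3), c(1, 1, 2))
  expect_equal(hausdorff(A, A), 0)
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_error(hausdorff(A, matrix(0, 0, 2)), "undefined")
  expect_error(hausdorff(matrix(FALSE, 4, 4), A), "undefined")
})

test_that("Hausdorff equals the double-loop oracle exactly on random sets", {
  set.seed(51)
  for (i in 1:30) {
    A <- rand_mask_points(60)
    B <- rand_mask_points(60)
    expect_identical(hausdorff(A, B), hausdorff_loop(A, B))
    expect_identical(hausdorff(A, B), hausdorff(B, A))
  }
})

test_that("boundary and full foreground sets give the same Hausdorff distance", {
  set.seed(52)
  for (i in 1:10) {
    a <- matrix(runif(16 * 16) > 0.6, 16, 16)
    b <- matrix(runif(16 * 16) > 0.6, 16, 16)
    if (!any(a) || !any(b)) next
    expect_equal(hausdorff(mask_boundary(a), mask_boundary(b)),
                 hausdorff(a, b))
  }
})

test_that("per-case evaluation aggregates classes per the report contract", {
  ref <- matrix(0L, 8, 8)
  ref[2:5, 2:5] <- 1L
  # identical prediction: DSC 1, HD 0 for every class
  r <- evaluate_case(ref, ref, 2L)
  expect_equal(r$per_class$dsc, c(1, 1))
  expect_equal(r$per_class$hd, c(0, 0))
  expect_equal(r$mean_dsc, 1)
  expect_equal(r$mean_hd, 0)
  # all-background prediction: foreground DSC 0, HD undefined and counted
  r0 <- evaluate_case(matrix(0L, 8, 8), ref, 2L)
  expect_equal(r0$per_class$dsc[2], 0)
  expect_true(is.na(r0$per_class$hd[2]))
  expect_identical(r0$n_hd_undefined, 1L)
  # hand-drawn shifted square: DSC and HD against the loop oracle
  pred <- matrix(0L, 8, 8)
  pred[3:6, 3:6] <- 1L
  r2 <- evaluate_case(pred, ref, 2L)
  expect_equal(r2$per_class$dsc[2], 2 * 9 / (16 + 16))
  expect_equal(r2$per_class$hd[2],
               hausdorff_loop(which(pred == 1L, arr.ind = TRUE),
                              which(ref == 1L, arr.ind = TRUE)))
})

test_that("metric reports serialise to CSV and JSON", {
  ref <- matrix(0L, 8, 8); ref[2:4, 2:4] <- 1L
  reports <- list(case_a = evaluate_case(ref, ref, 2L),
                  case_b = evaluate_case(matrix(0L, 8, 8), ref, 2L))
  csv <- file.path(tempdir(), "metrics.csv")
  js <- file.path(tempdir(), "metrics.json")
  reports_to_csv(reports, csv)
  reports_to_json(reports, js)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 4L)  # 2 cases x 2 classes
  expect_true(all(c("case_id", "class", "dsc", "hd", "hd_defined") %in%
                    names(tab)))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n_cases, 2L)
  expect_equal(parsed$mean_dsc, 0.5)
})

test_that("training objective decreases on a fixed toy batch", {
  set.seed(53)
  # a one-conv pixel classifier driven by the fused objective
  conv <- nn_conv2d(1, 3, 3)
  params <- module_params(conv)
  x <- hybridseg:::tensor_const(array(runif(12 * 12), c(12, 12, 1, 1)))
  y <- array(sample(0:2, 144, TRUE), c(12, 12, 1))
  losses <- numeric(50)
  for (s in 1:50) {
    hybridseg:::zero_grads(params)
    l <- hybridseg:::op_seg_loss(conv$fwd(x, TRUE), y)
    hybridseg:::backward(l)
    hybridseg:::sgd_step(params, lr = 0.05, momentum = 0.9,
                         weight_decay = 0)
    losses[s] <- as.numeric(l$value)
  }
  expect_lt(losses[50], losses[1])
  expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)))
})
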