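test_that("per-class comparison flags phantom classes", {
  pred <- list(length_mm = c(10, 20, 0, 5))
  truth <- list(class_mm = c(20, 10, 0, 0))
  cmp <- compare_class_lengths(pred, truth)
  expect_equal(cmp$error_mm, c(-10, 10, 0, 5))
  expect_equal(cmp$error_pct[1:2], c(-50, 100))
  expect_true(is.na(cmp$error_pct[4]))
  expect_equal(cmp$phantom, c(FALSE, FALSE, FALSE, TRUE))
  ident <- compare_class_lengths(list(length_mm = c(1, 2, 3, 4)),
                                 list(class_mm = c(1, 2, 3, 4)))
  expect_true(all(ident$error_mm == 0))
})

test_that("regression statistics follow their closed forms", {
  set.seed(5)
  truth <- runif(40, 10, 300)
  r1 <- regression_stats(truth, truth)
  expect_equal(r1$R2, 1)
  expect_equal(r1$nRMSE, 0)
  r0 <- regression_stats(rep(mean(truth), 40), truth)
  expect_equal(r0$R2, 0)
  delta <- 17
  r2 <- regression_stats(truth + delta, truth)
  sd_pop <- sqrt(mean((truth - mean(truth))^2))
  expect_equal(r2$nRMSE, delta / sd_pop)
  # scale equivariance
  r3 <- regression_stats(3 * (truth + delta), 3 * truth)
  expect_equal(r3$R2, r2$R2)
  expect_equal(r3$nRMSE, r2$nRMSE)
  expect_error(regression_stats(truth, rep(1, 40)), "variance")
})

test_that("mask metrics compute IoU and area errors", {
  A <- matrix(0L, 20, 20); A[1:10, 1:10] <- 1L
  expect_equal(mask_metrics(A, A)$iou, 1)
  B <- matrix(0L, 20, 20); B[11:20, 11:20] <- 1L
  expect_equal(mask_metrics(A, B)$iou, 0)
  # 10x10 squares shifted by 5: intersection 50, union 150
  C <- matrix(0L, 20, 20); C[1:10, 6:15] <- 1L
  m <- mask_metrics(A, C)
  expect_equal(m$iou, 1 / 3)
  expect_equal(m$area_error_pct, 0)
  expect_equal(m$iou, mask_metrics(C, A)$iou)  # symmetry
  e <- mask_metrics(matrix(0L, 5, 5), matrix(0L, 5, 5))
  expect_equal(e$iou, 1)
  expect_true(e$both_empty)
})

test_that("perspective shortening behaves as the projection model demands", {
  expect_equal(perspective_shortening(90), 0, tolerance = 1e-9)
  # horizontal segment, orthographic rotation average: 100 (1 - 2/pi)
  expect_equal(perspective_shortening(0), 100 * (1 - 2 / pi),
               tolerance = 0.01)
  sh <- vapply(seq(0, 90, by = 10), perspective_shortening, numeric(1))
  expect_true(all(diff(sh) <= 1e-9))      # monotone toward vertical
  # rotation averaging never exceeds the worst single view
  for (a in c(0, 30, 60)) {
    expect_lte(perspective_shortening(a),
               perspective_shortening(a, rotation_average = FALSE))
  }
  # pinhole model approaches the orthographic limit for a distant camera
  cal <- camera_calibration(mm_per_px = 0.5, axis_distance_mm = 1e6,
                            focal_length_px = 2e6)
  expect_equal(perspective_shortening(30, cal = cal),
               perspective_shortening(30), tolerance = 1e-3)
})
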