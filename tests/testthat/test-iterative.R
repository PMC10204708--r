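test_that("iteration plans validate their ordering", {
  plan <- iteration_plan(w_max = 17, h = 25)
  expect_equal(length(plan$steps), 3L)
  w <- vapply(plan$steps, function(s) s$w, numeric(1))
  expect_true(all(diff(w) > 0))
  rev <- iteration_plan(w_max = 17, direction = "reverse", h = 25)
  wr <- vapply(rev$steps, function(s) s$w, numeric(1))
  expect_true(all(diff(wr) < 0))
  expect_equal(rev$tau_min_px, c(wr[-1], 0))
  bad <- plan
  bad$steps <- bad$steps[c(2, 1, 3)]
  expect_error(run_iterations(matrix(0, 5, 5), matrix(1L, 5, 5), bad),
               "increasing")
})

test_that("a forward plan recovers both scales of the two-bar fixture", {
  img <- two_bar_image()
  RS <- (img > 0) * 1L
  out <- run_iterations(img, RS, iteration_plan(w_max = 17, h = 25))
  wm <- out$width_map
  small <- wm[wm$row <= 30, ]
  big <- wm[wm$row >= 60, ]
  expect_lt(abs(median(small$width_px) - 4), 1)
  expect_lt(abs(median(big$width_px) - 30), 1)
  # coverage of both centerlines within a 2-px band
  expect_gte(length(unique(small$col[abs(small$row - 21.5) <= 2])) / 160,
             0.95)
  expect_gte(length(unique(big$col[abs(big$row - 84.5) <= 2])) / 160, 0.95)
})

test_that("a reverse plan also covers both scales", {
  img <- two_bar_image()
  RS <- (img > 0) * 1L
  plan <- iteration_plan(w_max = 17, direction = "reverse", h = 25,
                         tau_min_px = c(10, 3.4, 1.5, 0))
  out <- run_iterations(img, RS, plan)
  wm <- out$width_map
  small <- wm[wm$row <= 30, ]
  big <- wm[wm$row >= 60, ]
  expect_gte(length(unique(small$col[abs(small$row - 21.5) <= 2])) / 160,
             0.95)
  expect_gte(length(unique(big$col[abs(big$row - 84.5) <= 2])) / 160, 0.95)
})

test_that("a single large-scale pass erases the small bar", {
  img <- two_bar_image()
  RS <- (img > 0) * 1L
  plan <- iteration_plan(w_max = 15, n_steps = 1, h = 100,
                         sigma = 15 / sqrt(3))
  out <- run_iterations(img, RS, plan)
  wm <- out$width_map
  expect_equal(sum(wm$row <= 30), 0)        # small bar gone
  expect_gt(sum(wm$row >= 60), 100)         # big bar found
})

test_that("deletion masks grow monotonically and the run is a fixed point", {
  img <- two_bar_image()
  RS <- (img > 0) * 1L
  plan <- iteration_plan(w_max = 17, h = 25)
  out <- run_iterations(img, RS, plan)
  Ds <- c(out$D_history, list(out$D))
  for (i in seq_len(length(Ds) - 1L)) {
    expect_true(all(Ds[[i + 1]][Ds[[i]] == 1L] == 1L))
  }
  again <- run_iterations(img, RS, plan, D = out$D)
  expect_equal(nrow(again$width_map), 0)
  # empty root-system mask: empty result
  empty <- run_iterations(img, RS * 0L, plan)
  expect_equal(nrow(empty$width_map), 0)
})

test_that("pixels are claimed once and earlier steps are never overwritten", {
  img <- two_bar_image()
  RS <- (img > 0) * 1L
  plan3 <- iteration_plan(w_max = 17, n_steps = 3, h = 25)
  out <- run_iterations(img, RS, plan3)
  wm <- out$width_map
  expect_false(any(duplicated(wm[, c("row", "col")])))
  # a plan truncated after two steps claims exactly the same early pixels
  plan2 <- plan3
  plan2$steps <- plan3$steps[1:2]
  plan2$tau_min_px <- plan3$tau_min_px[1:2]
  out2 <- run_iterations(img, RS, plan2)
  w12 <- wm[wm$source_step <= 2, ]
  expect_equal(w12[order(w12$row, w12$col), c("row", "col", "width_px")],
               out2$width_map[order(out2$width_map$row, out2$width_map$col),
                              c("row", "col", "width_px")],
               ignore_attr = TRUE)
})

test_that("postprocessing closes 1-px gaps, thins, and masks with RS", {
  H <- 30; W <- 61
  dashed <- matrix(0L, H, W)
  dashed[15, seq(1, W, by = 2)] <- 1L       # 1-px gaps
  RS <- matrix(1L, H, W)
  skel <- postprocess_centerlines(dashed, RS)
  expect_equal(max(EBImage::bwlabel(skel)), 1)  # one connected component
  # a 3-px-thick blob thins to a 1-px line
  blob <- matrix(0L, H, W)
  blob[14:16, 10:50] <- 1L
  skel2 <- postprocess_centerlines(blob, RS)
  expect_true(all(colSums(skel2[, 12:48]) <= 1))
  expect_gt(sum(skel2), 30)
  # pixels outside RS are removed
  RS2 <- RS; RS2[, 31:W] <- 0L
  skel3 <- postprocess_centerlines(blob, RS2)
  expect_equal(sum(skel3[, 32:W]), 0)
})

test_that("orientation correction yields the analytic tau factors", {
  H <- 80; W <- 80
  horiz <- matrix(0L, H, W); horiz[40, 10:70] <- 1L
  s1 <- orientation_correction(horiz, tile_size = 80)
  expect_equal(s1$tau_len, 1.0, tolerance = 1e-6)
  diag45 <- matrix(0L, H, W); diag45[cbind(10:70, 10:70)] <- 1L
  s2 <- orientation_correction(diag45, tile_size = 80)
  expect_equal(s2$tau_len, sqrt(2), tolerance = 1e-6)
  # 30-degree digital line
  deg30 <- matrix(0L, H, W)
  cols <- 10:70
  rows <- round(40 + (cols - 40) * tan(pi / 6))
  deg30[cbind(rows, cols)] <- 1L
  s3 <- orientation_correction(deg30, tile_size = 80)
  expect_equal(s3$tau_len, 1 / cos(pi / 6), tolerance = 0.02)
  # empty skeleton emits no segments
  expect_equal(nrow(orientation_correction(matrix(0L, 10, 10))), 0)
})

test_that("corrected lengths restore metric length of diagonal paths", {
  n <- 64
  horiz <- data.frame(row = rep(5L, n), col = seq_len(n), width_px = 1)
  skel_h <- matrix(0L, 10, n + 2)
  skel_h[cbind(horiz$row, horiz$col)] <- 1L
  segs_h <- orientation_correction(skel_h, tile_size = 32)
  wh <- corrected_lengths(horiz, segs_h, tile_size = 32)
  expect_equal(sum(wh$length_weight), n, tolerance = 1e-6)
  dg <- data.frame(row = seq_len(n) + 1L, col = seq_len(n) + 1L,
                   width_px = 1)
  skel_d <- matrix(0L, n + 2, n + 2)
  skel_d[cbind(dg$row, dg$col)] <- 1L
  segs_d <- orientation_correction(skel_d, tile_size = 32)
  wd <- corrected_lengths(dg, segs_d, tile_size = 32)
  expect_equal(sum(wd$length_weight), n * sqrt(2), tolerance = 1e-3)
  # tau is always in [1, sqrt(2)] and corrected >= raw count
  expect_true(all(wd$length_weight >= 1 - 1e-9 &
                    wd$length_weight <= sqrt(2) + 1e-9))
  # uncorrected counting under-measures a diagonal by ~29%
  expect_equal(diagonal_undermeasurement(), 100 * (1 - 1 / sqrt(2)),
               tolerance = 1e-6)
})
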