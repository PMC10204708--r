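test_that("blueness follows 3B - 2.4G - R with per-frame normalization", {
  expect_equal(blueness_map(flat_frame(0, 0, 255))$beta[1, 1], 765)
  bl <- blueness_map(rect_frame())
  expect_equal(bl$beta[1, 1], 3 * 190 - 2.4 * 55 - 35)
  expect_equal(bl$beta[30, 40], 3 * 160 - 2.4 * 170 - 180)
  expect_equal(max(bl$beta_norm), 255)
  # black pixel has beta 0 (and triggers the degenerate-normalization
  # warning); white has negative beta
  expect_warning(b0 <- blueness_map(flat_frame(0, 0, 0)), "blueness")
  expect_equal(b0$beta[1, 1], 0)
  expect_warning(b2 <- blueness_map(flat_frame(255, 255, 255)), "blueness")
  expect_true(all(b2$beta == -102))
  expect_true(all(b2$beta_norm == 0))
})

test_that("foreground thresholding matches the brute-force oracle and is
          monotone in T_beta", {
  set.seed(42)
  fr <- frame(array(runif(30 * 20 * 3, 0, 255), c(30, 20, 3)))
  bl <- blueness_map(fr)
  F <- segment_foreground(bl, 128)
  expect_equal(F, matrix(as.integer(bl$beta_norm < 128), 30, 20))
  F_small <- segment_foreground(bl, 60)
  expect_true(all(F[F_small == 1] == 1))   # larger threshold => superset
  # a uniformly saturated-blue frame is pure background
  expect_true(all(segment_foreground(blueness_map(flat_frame(0, 0, 255)),
                                     128) == 0))
})

test_that("label mask blanks exactly the requested rectangles", {
  L <- label_mask(c(40, 50))
  expect_true(all(L == 1))
  L1 <- label_mask(c(40, 50), list(c(5, 5, 10, 10)))
  expect_equal(sum(L1 == 0), 100)
  # overlapping rectangles: zero count equals the union area (brute force)
  regs <- list(c(3, 4, 12, 9), c(8, 8, 10, 10))
  L2 <- label_mask(c(40, 50), regs)
  ref <- matrix(0L, 40, 50)
  for (rg in regs) {
    for (x in seq(rg[1], rg[1] + rg[3] - 1)) {
      for (y in seq(rg[2], rg[2] + rg[4] - 1)) {
        ref[y + 1, x + 1] <- 1L
      }
    }
  }
  expect_equal(sum(L2 == 0), sum(ref))
  # out-of-bounds regions are clipped, not an error
  expect_equal(sum(label_mask(c(10, 10), list(c(8, 8, 10, 10))) == 0), 4)
})

test_that("stem mask inverts an external stem map", {
  fr <- rect_frame()
  expect_true(all(stem_mask(fr) == 1))
  f <- withr::local_tempfile(fileext = ".png")
  stem <- matrix(0, 60, 80); stem[1:10, 1:50] <- 1
  png::writePNG(stem, f)
  S <- stem_mask(fr, f)
  expect_equal(sum(S == 0), 500)
  expect_error(stem_mask(fr, function(fr) matrix(1, 2, 2)), "shape")
  expect_warning(stem_mask(fr, function(fr) matrix(0, 60, 80)), "empty")
})

test_that("mask combination is a pointwise AND with absorbing zeros", {
  set.seed(7)
  ms <- replicate(4, random_mask(15, 18), simplify = FALSE)
  M <- combine_masks(ms[[1]], ms[[2]], ms[[3]], ms[[4]])
  expect_equal(M, (ms[[1]] & ms[[2]] & ms[[3]] & ms[[4]]) * 1L)
  one <- matrix(1L, 15, 18)
  expect_equal(combine_masks(ms[[1]], one, one, one), ms[[1]])
  # M is a subset of every factor
  for (m in ms) expect_true(all(m[M == 1] == 1))
  expect_error(combine_masks(ms[[1]], one, one, matrix(1L, 3, 3)), "shapes")
})

test_that("refine_root_mask erodes with a disc and filters fragments", {
  M <- matrix(0L, 40, 40)
  M[11:30, 11:30] <- 1L                     # 20 x 20 square
  expect_equal(refine_root_mask(M, 0, 0), M)
  RS <- refine_root_mask(M, theta_px = 2, T_F = 0)
  expect_equal(sum(RS), 16 * 16)            # analytic erosion result
  expect_true(all(RS[13:28, 13:28] == 1))
  # increasing erosion is monotone non-increasing in pixel count
  counts <- vapply(0:3, function(t) sum(refine_root_mask(M, t, 0)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # small fragments are removed
  M2 <- M; M2[2:2, 2:3] <- 1L               # 2-px blob
  M2[5, 38] <- 1L                           # isolated pixel
  RS2 <- refine_root_mask(M2, 0, T_F = 10)
  expect_equal(sum(RS2), 400)
})

test_that("Canny blur mask keeps sharp structures and drops blurred ones", {
  g <- bar_image(10, H = 60, W = 80)
  C <- blur_mask(g, segmentation_params(canny_low = 5, canny_high = 20,
                                        blur_dilation_px = 5))
  rows <- attr(g, "rows")
  expect_true(all(C[rows[1]:rows[2], 20:60] == 1))   # bar interior kept
  expect_true(all(blur_mask(matrix(50, 40, 40)) == 0))  # no edges at all
  # heavy box blur erases the edges of the bar
  k <- matrix(1 / 441, 21, 21)
  gb <- EBImage::filter2(g, k)
  Cb <- blur_mask(gb, segmentation_params(canny_low = 5, canny_high = 20,
                                          blur_dilation_px = 5))
  expect_true(sum(Cb[rows[1]:rows[2], 20:60]) <
                0.2 * sum(C[rows[1]:rows[2], 20:60]))
})

test_that("segment_root_system produces a consistent mask set", {
  fr <- rect_frame()
  ms <- segment_root_system(fr, segmentation_params(use_blur_mask = FALSE))
  expect_s3_class(ms, "mask_set")
  expect_equal(ms$M, combine_masks(ms$F, ms$S, ms$L, ms$C))
  expect_true(all(ms$M[ms$RS == 1] == 1))   # RS subset of M
  expect_true(all(ms$RS[25:35, 35:45] == 1))  # rectangle interior kept
  expect_true(ms$RS[5, 5] == 0)             # blue background removed
})
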