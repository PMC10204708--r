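test_that("the saliency threshold matches a numeric convolution oracle", {
  # oracle: convolve an ideal bar profile with the analytic second-derivative
  # Gaussian kernel on a fine grid and read off the center response
  num_u <- function(w, sigma, h) {
    dx <- 0.002
    # midpoint sampling so the bar's edges are not double-counted
    x <- seq(-8 * sigma - w + dx / 2, 8 * sigma + w, by = dx)
    f <- ifelse(abs(x) <= w, h, 0)
    g2 <- (x^2 / sigma^4 - 1 / sigma^2) *
      exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
    abs(sum(g2 * f) * dx)
  }
  for (p in list(c(3, 1, 50), c(6, 2, 50), c(2.5, 1.2, 80))) {
    expect_equal(ridge_threshold_u(p[1], p[2], p[3]),
                 num_u(p[1], p[2], p[3]), tolerance = 1e-4)
  }
  expect_equal(ridge_threshold_u(3, 1, 50), 1.329555, tolerance = 1e-6)
  expect_equal(ridge_threshold_u(6, 2, 50), 0.3323886, tolerance = 1e-6)
  expect_equal(ridge_threshold_u(3, 1, 0), 0)
  # strictly linear in h
  expect_equal(ridge_threshold_u(3, 1, 100), 2 * ridge_threshold_u(3, 1, 50))
  expect_error(ridge_threshold_u(-1, 1, 50))
})

test_that("Gaussian kernel sets are correctly normalized", {
  for (s in c(1, 1.7, 4)) {
    k <- gaussian_kernels(s)
    expect_equal(sum(k$g0), 1, tolerance = 1e-6)
    expect_equal(sum(k$g1), 0, tolerance = 1e-6)
    expect_equal(sum(k$g2), 0, tolerance = 1e-6)
    expect_equal(k$radius, ceiling(3.5 * s))
  }
})

test_that("ridge params warn when the scale rule is violated", {
  expect_warning(ridge_params(w = 6, sigma = 1, h = 10), "sigma")
  expect_silent(ridge_params(w = 3, sigma = 1, h = 10))
})

test_that("a synthetic bar yields one centerline on its axis", {
  img <- bar_image(10)
  p <- ridge_params(w = 5, sigma = 5 / 3, h = 100)
  lines <- detect_ridges(img, p)
  expect_gt(length(lines), 0)
  pts <- do.call(rbind, lines)
  expect_true(all(abs(pts[, "subr"] - attr(img, "center_row")) <= 0.5 + 1e-6))
  # sub-pixel residual to the true axis
  expect_lt(sqrt(mean((pts[, "subr"] - attr(img, "center_row"))^2)), 0.5)
  # constant image: nothing
  expect_length(detect_ridges(matrix(80, 50, 50), p), 0)
  # exclusion mask covering the bar: nothing
  excl <- matrix(0L, nrow(img), ncol(img))
  excl[attr(img, "rows")[1]:attr(img, "rows")[2], ] <- 1L
  expect_length(detect_ridges(img, p, exclusion = excl), 0)
})

test_that("width recovery is within 1 px on noiseless bars 4-40 px", {
  for (fw in c(4, 8, 12, 20, 28, 34, 40)) {
    wt <- fw / 2
    img <- bar_image(fw)
    p <- ridge_params(w = wt, sigma = max(wt / 3, 1), h = 100)
    wdf <- measure_widths(detect_ridges(img, p))
    expect_gt(nrow(wdf), 50)
    expect_lt(abs(median(wdf$width_px) - fw), 1)
  }
})

test_that("doubling contrast with doubled h leaves line geometry unchanged", {
  img <- bar_image(10)
  l1 <- detect_ridges(img, ridge_params(5, 5 / 3, h = 100))
  l2 <- detect_ridges(img * 2, ridge_params(5, 5 / 3, h = 200))
  geom <- function(l) lapply(l, function(m) m[, 1:6])
  expect_equal(geom(l1), geom(l2))
})

test_that("asymmetric side contrasts barely displace the centerline", {
  img <- matrix(0, 60, 120)
  img[36:60, ] <- 40          # brighter lower background
  img[26:35, ] <- 100         # bar: contrast 100 above, 60 below
  wdf <- measure_widths(detect_ridges(img, ridge_params(5, 5 / 3, h = 60)))
  expect_gt(nrow(wdf), 50)
  expect_lt(abs(median(wdf$subr) - 30.5), 1)
  expect_lt(abs(median(wdf$width_px) - 10), 1.5)
})

test_that("edges corrupted by a crossing structure are interpolated", {
  img <- matrix(0, 80, 160)
  img[36:45, ] <- 100          # horizontal 10-px bar
  img[, 76:85] <- 100          # vertical 10-px bar crossing it
  wdf <- measure_widths(detect_ridges(img, ridge_params(5, 5 / 3, h = 100)))
  horiz <- wdf[abs(wdf$subr - 40.5) < 2, ]
  near <- horiz[horiz$col >= 70 & horiz$col <= 91, ]
  far <- horiz[horiz$col < 60 | horiz$col > 100, ]
  expect_gt(nrow(near), 0)
  expect_true(any(near$interpolated))      # filled in, and flagged
  expect_true(all(near$width_px >= min(far$width_px) - 1 &
                    near$width_px <= max(far$width_px) + 3))
})
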