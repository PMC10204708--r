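test_that("class boundaries are lower-inclusive half-open intervals", {
  expect_equal(width_class(c(0.5, 1.99, 2.0, 5.99, 6.0, 19.99, 20, 25)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("classify_widths bins constituent length by local diameter", {
  wmap <- data.frame(width_px = c(rep(1.5, 10), rep(10, 10)),
                     length_weight = 1)
  d <- classify_widths(wmap, cal = camera_calibration(mm_per_px = 1))
  expect_equal(d$length_mm, c(10, 0, 10, 0))
  expect_equal(d$fraction_pct, c(50, 0, 50, 0))
  expect_equal(d$total_length_mm, 20)
  expect_equal(sum(d$fraction_pct), 100)
  # fine histogram is a probability distribution consistent with classes
  expect_equal(sum(d$fine_histogram$probability), 1, tolerance = 1e-9)
  rebin <- tapply(d$fine_histogram$probability,
                  width_class(d$fine_histogram$diameter_mm),
                  sum)
  expect_equal(as.numeric(rebin) * d$total_length_mm,
               d$length_mm[d$length_mm > 0], tolerance = 1e-9)
})

test_that("classification conserves total corrected length", {
  set.seed(3)
  wmap <- data.frame(width_px = runif(500, 1, 50),
                     length_weight = runif(500, 1, sqrt(2)))
  cal <- camera_calibration(mm_per_px = 0.7)
  d <- classify_widths(wmap, cal = cal)
  expect_equal(sum(d$length_mm), sum(wmap$length_weight) * 0.7,
               tolerance = 1e-9)
  # permutation invariance
  d2 <- classify_widths(wmap[sample(nrow(wmap)), ], cal = cal)
  expect_equal(d$length_mm, d2$length_mm)
})

test_that("an empty width map yields a flagged all-zero distribution", {
  d <- classify_widths(data.frame(width_px = numeric(),
                                  length_weight = numeric()))
  expect_true(d$empty)
  expect_equal(d$length_mm, rep(0, 4))
  expect_true(all(is.na(d$fraction_pct)))
})

test_that("frame aggregation supports mean, max and percentile modes", {
  mk <- function(lens) {
    classify_widths(data.frame(width_px = rep(c(1, 4, 10, 25),
                                              times = lens),
                               length_weight = 1),
                    cal = camera_calibration(mm_per_px = 1))
  }
  d1 <- mk(c(10, 0, 0, 0))
  d2 <- mk(c(0, 10, 0, 0))
  agg <- aggregate_frames(list(d1, d2), mode = "mean")
  expect_equal(agg$fraction_pct, c(50, 50, 0, 0))
  # idempotence on identical inputs
  same <- aggregate_frames(list(d1, d1, d1), mode = "mean")
  expect_equal(same$fraction_pct, d1$fraction_pct)
  expect_equal(same$length_mm, d1$length_mm)
  # max over frames per class
  a <- mk(c(0, 0, 10, 0)); b <- mk(c(0, 0, 30, 0)); c3 <- mk(c(0, 0, 20, 0))
  mx <- aggregate_frames(list(a, b, c3), mode = "max")
  expect_equal(mx$length_mm[3], 30)
  pc <- aggregate_frames(list(a, b, c3), mode = "percentile", p = 50)
  expect_equal(pc$length_mm[3], 20)
  # empty frames are dropped from the mean with a count
  e <- classify_widths(data.frame(width_px = numeric(),
                                  length_weight = numeric()))
  agg2 <- aggregate_frames(list(d1, e), mode = "mean")
  expect_equal(agg2$n_frames, 1L)
  expect_equal(agg2$n_frames_dropped, 1L)
  expect_error(aggregate_frames(list()), "no distributions")
})

test_that("growth dynamics reports box statistics per class and week", {
  mk_frac <- function(f) {
    structure(list(fraction_pct = f, length_mm = f, empty = FALSE,
                   scheme = diameter_classes()),
              class = "diameter_distribution")
  }
  one <- list(`5` = list(mk_frac(c(70, 20, 10, 0))))
  g1 <- growth_dynamics(one)
  expect_equal(g1$median[g1$class == 1], 70)
  # constructed monotone decline of class 1
  weeks <- lapply(seq(80, 30, by = -10), function(base) {
    lapply(0:2, function(j) mk_frac(c(base + j, 100 - base - j, 0, 0)))
  })
  names(weeks) <- as.character(seq_along(weeks) + 4)
  g <- growth_dynamics(weeks)
  med1 <- g$median[g$class == 1]
  expect_true(all(diff(med1) < 0))
  # per-week medians over classes sum to ~100
  sums <- tapply(g$median, g$week, sum)
  expect_true(all(sums >= 95 & sums <= 105))
})
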