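test_that("analytic truth is exact for simple profiles", {
  ax <- cbind(x = rep(0, 3), y = c(0, 50, 100))
  # constant 4 mm over 100 mm: all in fine bin 4-5, class 2
  r <- root_spec("II", ax, data.frame(s = c(0, 100), d = c(4, 4)), 4)
  tr <- root_truth(r)
  expect_equal(unname(tr$fine[["4-5"]]), 100)
  expect_equal(tr$class_mm, c(0, 100, 0, 0))
  # linear taper 8 -> 0 over 80 mm: 10 mm of arc per 1-mm bin
  r2 <- root_spec("III", ax[, ], data.frame(s = c(0, 80), d = c(8, 0)), 8)
  tr2 <- root_truth(r2)
  expect_equal(unname(tr2$fine[["2-3"]]), 10)
  expect_equal(tr2$class_mm, c(20, 40, 20, 0))
  expect_equal(tr2$total_mm, 80)
  # fine bins merge losslessly into classes
  expect_equal(sum(tr2$fine), sum(tr2$class_mm))
})

test_that("scene truth is additive over roots", {
  sc <- generate_root_system(5, "II", seed = 11)
  per_root <- lapply(sc$roots, root_truth)
  summed <- Reduce(`+`, lapply(per_root, function(t) t$class_mm))
  expect_equal(sc$truth$class_mm, summed, tolerance = 1e-9)
})

test_that("identical seeds reproduce scenes bit for bit", {
  a <- generate_single_root("II", seed = 5)
  b <- generate_single_root("II", seed = 5)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
  c1 <- generate_root_system(4, "III", seed = 9)
  c2 <- generate_root_system(4, "III", seed = 9)
  expect_identical(c1$frame$pixels, c2$frame$pixels)
})

test_that("ground truth is independent of the rendering resolution", {
  a <- generate_root_system(3, "II", mm_per_px = 0.6, seed = 21)
  b <- generate_root_system(3, "II", mm_per_px = 1.2, seed = 21)
  expect_equal(a$truth$fine, b$truth$fine, tolerance = 1e-12)
})

test_that("single-root scenes respect the type class bounds", {
  t1 <- generate_single_root("I", seed = 3)
  expect_equal(t1$truth$class_mm[2:4], rep(0, 3))
  expect_gt(t1$truth$class_mm[1], 0)
  t4 <- generate_single_root("IV", seed = 3)
  expect_true(all(t4$truth$class_mm > 0))  # taper crosses every class
  expect_error(root_spec("I", cbind(0, c(0, 10)),
                         data.frame(s = c(0, 10), d = c(5, 0)), 5),
               "max diameter")
  expect_error(root_spec("IV", cbind(0, c(0, 10)),
                         data.frame(s = c(0, 10), d = c(50, 0)), 50),
               "45 mm")
})

test_that("a one-root system equals the single-root machinery", {
  sc <- generate_root_system(1, "III", seed = 8)
  expect_length(sc$roots, 1)
  expect_equal(sc$truth$class_mm,
               root_truth(sc$roots[[1]])$class_mm)
})

test_that("the growth series has the prescribed class timing", {
  ser <- generate_time_series(n_subsets = 2, seed = 2)
  wk <- ser$scenes$week
  cls <- t(vapply(ser$truths, function(t) t$class_mm, numeric(4)))
  # week 2: only fibrous roots
  expect_true(all(cls[wk == 2, 2:4] == 0))
  # class 4 appears exactly from the configured week on
  expect_true(all(cls[wk < 10, 4] == 0))
  expect_true(any(cls[wk == 10, 4] > 0))
  # weekly truth grows overall
  tot <- tapply(rowSums(cls), wk, mean)
  expect_gt(tot[["13"]], tot[["3"]])
})

test_that("stratified subsets preserve root-type proportions within 1", {
  ser <- generate_time_series(n_subsets = 3, seed = 4)
  for (si in which(ser$scenes$week %in% c(6, 13))) {
    wkk <- ser$scenes$week[si]
    present <- which(vapply(ser$trajectories,
                            function(tr) tr$emergence <= wkk, logical(1)))
    cur <- vapply(ser$trajectories[present], function(tr) {
      c("I", "II", "III", "IV")[width_class(
        rootridge:::diameter_at_week(tr, wkk))]
    }, character(1))
    sel <- ser$subsets[[si]]
    sel_types <- cur[match(sel, present)]
    for (tp in unique(cur)) {
      expected <- 17 * sum(cur == tp) / length(present)
      expect_lte(abs(sum(sel_types == tp) - expected), 1)
    }
  }
})

test_that("rendered axis length matches the analytic arc length within 3%", {
  sc <- generate_single_root("II", seed = 14)
  m <- measure_scene(sc, h = 40)
  expect_lt(abs(m$distribution$total_length_mm - sc$truth$total_mm) /
              sc$truth$total_mm, 0.03)
})

test_that("scene datasets round-trip to disk as text-adjacent formats", {
  dir <- withr::local_tempdir()
  scenes <- list(generate_single_root("II", seed = 1))
  manifest <- write_scene_dataset(scenes, dir)
  expect_true(file.exists(manifest))
  expect_true(file.exists(file.path(dir, "scene_001.png")))
  truth <- jsonlite::read_json(file.path(dir, "scene_001.json"))
  expect_equal(unlist(truth$class_mm), scenes[[1]]$truth$class_mm,
               tolerance = 1e-9)
  long <- read.csv(file.path(dir, "truth_long.csv"))
  expect_equal(sum(long$length_mm), scenes[[1]]$truth$total_mm,
               tolerance = 1e-9)
})
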