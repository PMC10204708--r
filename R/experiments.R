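#' @name experiments
#' @title Simulation-based validation experiments
#' @description
#' Drivers that reproduce the three simulation validation studies at
#' configurable scale: single roots per type, one-root-type systems at
#' video-box resolution, and a weekly growth series. Each driver generates
#' seeded synthetic scenes, runs the forward pipeline and returns pooled
#' predicted vs. true per-class constituent lengths together with the
#' regression statistics.
NULL

# default forward plan for a scene: the ladder top is set from the scene's
# largest root diameter (the analyst knows the rough maximum in practice)
scene_plan <- function(scene, h = 25, n_steps = 3L, direction = "forward") {
  dmax <- max(vapply(scene$roots, function(r) r$max_diameter_mm, numeric(1)))
  w_max <- 1.15 * dmax / scene$mm_per_px / 2
  w_max <- max(w_max, 2.5)
  # diameters below 3 px are unresolvable; measurements there come out one
  # class too thick, so they are suppressed rather than misclassified
  iteration_plan(w_max = w_max, w_min = 1.5, n_steps = n_steps,
                 direction = direction, h = h, min_width_px = 2.5)
}

# still-image segmentation for clean synthetic scenes
scene_seg <- function() {
  segmentation_params(T_beta = 128, use_blur_mask = FALSE, theta_px = 0,
                      T_F = 0)
}

#' Measure a synthetic scene with the forward pipeline
#'
#' @param scene a `root_scene`.
#' @param h ridge contrast parameter for the plan.
#' @param n_steps iteration steps.
#' @param direction iteration direction.
#' @return A `root_measurement` (with `$truth` attached).
#' @export
measure_scene <- function(scene, h = 25, n_steps = 3L,
                          direction = "forward") {
  measure_roots(scene, plan = scene_plan(scene, h = h, n_steps = n_steps,
                                         direction = direction),
                seg = scene_seg())
}

pool_row <- function(m, classes, ...) {
  data.frame(..., class = classes, pred_mm = m$distribution$length_mm[classes],
             truth_mm = m$truth$class_mm[classes])
}

#' Single-root validation experiment
#'
#' `n_per_type` synthetic single roots of each type I-IV at high resolution
#' (type-I roots at least 3 px wide), analysed with the forward plan;
#' predicted per-class constituent lengths are pooled over all scenes and
#' classes 1-4 and regressed against the analytic truth.
#'
#' @param n_per_type scenes per root type.
#' @param seed integer seed.
#' @param h ridge contrast parameter.
#' @return List with `data` (pooled data frame) and `stats`
#'   (a [regression_stats()] report).
#' @export
experiment_single_roots <- function(n_per_type = 50, seed = 1L, h = 25) {
  rows <- list()
  types <- c("I", "II", "III", "IV")
  for (ti in seq_along(types)) {
    for (i in seq_len(n_per_type)) {
      sc <- generate_single_root(types[ti],
                                 seed = seed + 7919L * ti + i)
      m <- measure_scene(sc, h = h)
      rows[[length(rows) + 1L]] <- pool_row(m, 1:4, type = types[ti],
                                            scene = i)
    }
  }
  d <- do.call(rbind, rows)
  list(data = d, stats = regression_stats(d$pred_mm, d$truth_mm))
}

#' One-root-type system validation experiment
#'
#' Root systems containing a single root type (II, III or IV), rendered at
#' video-box resolution (class-1 diameters at most ~2 px) with overlapping
#' root bases. Regression pools classes 2-4 (class 1 is unresolvable at
#' this resolution).
#'
#' @param n_per_type systems per type.
#' @param n_roots named per-type root counts; the defaults reflect typical
#'   excavated cassava crowns (transition roots are numerous, storage roots
#'   number about 3-10).
#' @param seed integer seed.
#' @param mm_per_px video-box resolution (0.6 mm/px puts the class-1/2
#'   boundary at 3.3 px).
#' @param h ridge contrast parameter.
#' @return List with `data` and `stats` as in
#'   [experiment_single_roots()].
#' @export
experiment_one_type <- function(n_per_type = 5,
                                n_roots = c(II = 16, III = 12, IV = 8),
                                seed = 1L, mm_per_px = 0.6, h = 25) {
  rows <- list()
  types <- c("II", "III", "IV")
  for (ti in seq_along(types)) {
    for (i in seq_len(n_per_type)) {
      sc <- generate_root_system(n_roots[[types[ti]]], types[ti],
                                 mm_per_px = mm_per_px,
                                 seed = seed + 104729L * ti + i)
      m <- measure_scene(sc, h = h)
      rows[[length(rows) + 1L]] <- pool_row(m, 2:4, type = types[ti],
                                            scene = i)
    }
  }
  d <- do.call(rbind, rows)
  list(data = d, stats = regression_stats(d$pred_mm, d$truth_mm))
}

#' Time-series validation experiment
#'
#' Weekly growth series (weeks 2-13): stratified subsets of 17 roots are
#' drawn from an 80-root master system each week and analysed at video-box
#' resolution. Regression pools classes 2-4 over all weeks and subsets.
#'
#' @param n_subsets scenes per week.
#' @param seed integer seed.
#' @param weeks week vector.
#' @param h ridge contrast parameter.
#' @return List with `series`, `data` and `stats`.
#' @export
experiment_time_series <- function(n_subsets = 5, seed = 1L, weeks = 2:13,
                                   h = 25) {
  series <- generate_time_series(weeks = weeks, n_subsets = n_subsets,
                                 seed = seed)
  rows <- list()
  for (si in seq_len(nrow(series$scenes))) {
    sc <- render_series_scene(series, si)
    m <- measure_scene(sc, h = h)
    rows[[length(rows) + 1L]] <- pool_row(m, 2:4,
                                          week = series$scenes$week[si],
                                          subset = series$scenes$subset[si])
  }
  d <- do.call(rbind, rows)
  list(series = series, data = d,
       stats = regression_stats(d$pred_mm, d$truth_mm))
}

#' Diagonal length under-measurement of uncorrected pixel counting
#'
#' Builds a 45-degree digital line, estimates its tile orientations and
#' compares plain pixel counting with the orientation-corrected length:
#' counting pixels under-measures a diagonal by `1 - 1/sqrt(2)` (~29%).
#'
#' @param n line length in pixels.
#' @return Under-measurement in percent.
#' @export
diagonal_undermeasurement <- function(n = 128) {
  skel <- matrix(0L, n + 2L, n + 2L)
  skel[cbind(seq_len(n) + 1L, seq_len(n) + 1L)] <- 1L
  segs <- orientation_correction(skel, tile_size = 32)
  wm <- data.frame(row = seq_len(n) + 1L, col = seq_len(n) + 1L,
                   width_px = 1)
  wm <- corrected_lengths(wm, segs, tile_size = 32)
  100 * (1 - nrow(wm) / sum(wm$length_weight))
}
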