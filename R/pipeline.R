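#' Measure the root diameter distribution of a frame
#'
#' The full analysis of one image: segmentation into the root-system mask,
#' iterative multi-scale ridge detection with per-pixel width measurement,
#' centerline postprocessing (gap closing, thinning, background masking),
#' orientation-based length correction, and classification of the corrected
#' centerline lengths into diameter classes.
#'
#' @param fr a [frame()] or a `root_scene` (whose calibration is then taken
#'   from the scene unless `cal` is given).
#' @param plan an [iteration_plan()]; required.
#' @param cal a [camera_calibration()].
#' @param seg a [segmentation_params()]; the default bypasses the blur mask
#'   (still image) and uses no erosion.
#' @param scheme a [diameter_classes()] scheme.
#' @param tile_size tile edge for the orientation correction (px).
#' @return An object of class `root_measurement`: `distribution`
#'   (a `diameter_distribution`), `width_map` (data frame with `row, col,
#'   width_px, width_mm, length_weight, class, source_step`), `skeleton`,
#'   `masks`, `plan`, `cal`, and (for scenes) `truth`.
#' @export
measure_roots <- function(fr, plan, cal = NULL,
                          seg = segmentation_params(use_blur_mask = FALSE),
                          scheme = diameter_classes(), tile_size = 32) {
  truth <- NULL
  if (inherits(fr, "root_scene")) {
    if (is.null(cal)) cal <- camera_calibration(mm_per_px = fr$mm_per_px)
    truth <- fr$truth
    fr <- fr$frame
  }
  stopifnot(inherits(fr, "root_frame"), inherits(plan, "iteration_plan"))
  if (is.null(cal)) cal <- camera_calibration()
  masks <- segment_root_system(fr, seg)
  gray <- to_gray(fr)
  raw <- run_iterations(gray, masks$RS, plan)
  skel <- postprocess_centerlines(raw$centerline, masks$RS)
  wm <- transfer_widths(skel, raw)
  segs <- orientation_correction(skel, tile_size = tile_size)
  wm <- corrected_lengths(wm, segs, tile_size = tile_size)
  dist <- classify_widths(wm, scheme, cal)
  if (nrow(wm)) {
    wm$width_mm <- px_to_mm(wm$width_px, cal)
    wm$class <- width_class(wm$width_mm, scheme)
  } else {
    wm$width_mm <- numeric(0)
    wm$class <- integer(0)
  }
  structure(
    list(distribution = dist, width_map = wm, skeleton = skel,
         masks = masks, segments = segs, plan = plan, cal = cal,
         truth = truth, frame = fr),
    class = "root_measurement"
  )
}

#' @export
print.root_measurement <- function(x, ...) {
  cat("Root width analysis\n")
  cat(sprintf("  centerline pixels: %d\n", nrow(x$width_map)))
  print(x$distribution)
  invisible(x)
}

#' @export
summary.root_measurement <- function(object, ...) {
  x <- object
  cat("Root width analysis summary\n")
  cat(sprintf("  image: %d x %d px at %.3g mm/px\n",
              nrow(x$skeleton), ncol(x$skeleton), x$cal$mm_per_px))
  cat(sprintf("  root-system mask: %d px (%.1f%% of frame)\n",
              sum(x$masks$RS), 100 * mean(x$masks$RS)))
  cat(sprintf("  plan: %s, %d steps\n", x$plan$direction,
              length(x$plan$steps)))
  print(x$distribution)
  if (!is.null(x$truth)) {
    cat("  vs. ground truth:\n")
    print(compare_class_lengths(x$distribution, x$truth))
  }
  invisible(x)
}

#' @export
coef.root_measurement <- function(object, ...) {
  object$distribution$length_mm
}

#' Plot a root measurement overlay
#'
#' The frame with detected centerlines coloured by diameter class
#' (class 1 purple, 2 green, 3 blue, 4 red).
#'
#' @param x a `root_measurement`.
#' @param ... passed to [graphics::rasterImage()] plotting setup.
#' @export
plot.root_measurement <- function(x, ...) {
  img <- overlay_image(x)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(img)), c(0, nrow(img)), type = "n", asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "detected root centerlines by diameter class")
  graphics::rasterImage(img, 0, 0, ncol(img), nrow(img), ...)
  invisible(x)
}

class_colors <- function() {
  rbind(c(160, 32, 240), c(0, 200, 0), c(30, 100, 255), c(230, 30, 30)) / 255
}

overlay_image <- function(x) {
  img <- x$frame$pixels / 255
  wm <- x$width_map
  cols <- class_colors()
  for (k in seq_len(nrow(wm))) {
    cl <- min(wm$class[k], 4L)
    img[wm$row[k], wm$col[k], ] <- cols[cl, ]
  }
  img
}

#' Write the per-frame width map as CSV
#'
#' Columns `frame, row, col, width_px, width_mm, length_weight, class`.
#'
#' @param measurement a `root_measurement`.
#' @param path output CSV path.
#' @param frame_id frame identifier written into the first column.
#' @export
write_width_csv <- function(measurement, path, frame_id = 0L) {
  wm <- measurement$width_map
  utils::write.csv(
    data.frame(frame = frame_id, row = wm$row, col = wm$col,
               width_px = wm$width_px, width_mm = wm$width_mm,
               length_weight = wm$length_weight, class = wm$class),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a per-plant JSON summary
#'
#' @param distribution a `diameter_distribution` (usually aggregated).
#' @param path output path.
#' @param plant_id,week identifiers.
#' @param n_frames number of frames behind the distribution.
#' @export
write_summary_json <- function(distribution, path, plant_id = "plant",
                               week = NA, n_frames = 1L) {
  jsonlite::write_json(
    list(plant_id = plant_id, week = week,
         length_mm = distribution$length_mm,
         fraction_pct = distribution$fraction_pct,
         total_length_mm = distribution$total_length_mm,
         n_frames = n_frames),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Analyze a list of frames and aggregate over perspectives
#'
#' Convenience wrapper: [measure_roots()] on every frame, then
#' [aggregate_frames()] over the per-frame distributions.
#'
#' @param frames list of frames (e.g. from [load_frames()]).
#' @param plan,cal,seg,scheme as in [measure_roots()].
#' @param mode aggregation mode, see [aggregate_frames()].
#' @return List with `aggregate` (a `diameter_distribution`) and
#'   `per_frame` (list of `root_measurement`s).
#' @export
analyze_frames <- function(frames, plan, cal = NULL,
                           seg = segmentation_params(),
                           scheme = diameter_classes(), mode = "mean") {
  per <- lapply(frames, measure_roots, plan = plan, cal = cal, seg = seg,
                scheme = scheme)
  agg <- aggregate_frames(lapply(per, function(m) m$distribution),
                          mode = mode)
  list(aggregate = agg, per_frame = per)
}
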