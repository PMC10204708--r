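#' Per-class error between a prediction and the ground truth
#'
#' Signed errors `pred - truth` per diameter class, in mm and in percent of
#' the truth. A class with zero truth but positive prediction is flagged as
#' a "phantom class" (a misclassification into a class that should not
#' exist).
#'
#' @param pred a `diameter_distribution`.
#' @param truth a [root_truth()] (or any list with `class_mm`).
#' @return Data frame `class, pred_mm, truth_mm, error_mm, error_pct,
#'   phantom`.
#' @export
compare_class_lengths <- function(pred, truth) {
  p <- pred$length_mm
  t <- truth$class_mm
  stopifnot(length(p) == length(t))
  err <- p - t
  pct <- ifelse(t > 0, 100 * err / t, NA_real_)
  data.frame(class = seq_along(p), pred_mm = p, truth_mm = t,
             error_mm = err, error_pct = pct,
             phantom = t == 0 & p > 0)
}

#' Regression statistics of predicted vs. true values
#'
#' Agreement statistics about the identity line: `R2 = 1 - SSE/SST` with
#' `SSE = sum((pred - truth)^2)` and `SST` the total sum of squares of the
#' truth; `nRMSE = RMSE / sd(truth)` with the population (n-denominator)
#' standard deviation. The slope/intercept of the least-squares fit of pred
#' on truth are reported alongside.
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @return An object of class `regression_report`.
#' @export
regression_stats <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  if (stats::var(truth) == 0) stop("truth values have zero variance")
  n <- length(pred)
  sse <- sum((pred - truth)^2)
  sst <- sum((truth - mean(truth))^2)
  rmse <- sqrt(sse / n)
  sd_pop <- sqrt(sst / n)
  fit <- stats::lm.fit(cbind(1, truth), pred)
  structure(
    list(R2 = 1 - sse / sst, nRMSE = rmse / sd_pop, n = n,
         intercept = unname(fit$coefficients[1]),
         slope = unname(fit$coefficients[2])),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> n = %d, R2 = %.4f, nRMSE = %.4f, fit: %.3f + %.3f x\n",
    x$n, x$R2, x$nRMSE, x$intercept, x$slope))
  invisible(x)
}

#' Binary mask comparison metrics
#'
#' Intersection over union and the absolute area error (percent of the true
#' area). Two empty masks are defined as identical (`iou = 1`, flagged).
#'
#' @param true_mask,pred_mask binary matrices of equal shape.
#' @return An object of class `mask_comparison`.
#' @export
mask_metrics <- function(true_mask, pred_mask) {
  stopifnot(all(dim(true_mask) == dim(pred_mask)))
  a <- true_mask > 0
  b <- pred_mask > 0
  inter <- sum(a & b)
  uni <- sum(a | b)
  area_true <- sum(a)
  area_pred <- sum(b)
  both_empty <- uni == 0
  structure(
    list(iou = if (both_empty) 1 else inter / uni,
         area_true = area_true, area_pred = area_pred,
         area_error_pct = if (area_true > 0)
           100 * abs(area_pred - area_true) / area_true else NA_real_,
         both_empty = both_empty),
    class = "mask_comparison"
  )
}

#' @export
print.mask_comparison <- function(x, ...) {
  cat(sprintf("<mask_comparison> IoU = %.4f, area %d vs %d px (%.2f%% error)\n",
              x$iou, x$area_true, x$area_pred,
              if (is.na(x$area_error_pct)) 0 else x$area_error_pct))
  invisible(x)
}

#' Perspective shortening of inclined root segments
#'
#' Under a turntable imaging geometry, a root segment inclined by
#' `inclination_deg` away from the (vertical) rotation axis appears
#' shortened in the image. With rotation averaging the apparent length is
#' the mean projected length over a full revolution. The default camera
#' model is the orthographic limit (valid when the camera-axis distance is
#' large relative to the root system); supplying a `camera_calibration` with
#' `focal_length_px` switches to a pinhole projection of a unit segment
#' centred on the axis.
#'
#' @param inclination_deg inclination in `[0, 90]` degrees; 90 = parallel to
#'   the rotation axis (vertical, no shortening), 0 = horizontal.
#' @param cal optional [camera_calibration()] with `focal_length_px` for the
#'   pinhole model.
#' @param rotation_average average over a full rotation (`TRUE`) or report
#'   the worst single view (`FALSE`).
#' @param n_angles rotation grid size for the numeric average.
#' @return Shortening in percent: `100 * (1 - apparent/true)`.
#' @export
perspective_shortening <- function(inclination_deg, cal = NULL,
                                   rotation_average = TRUE, n_angles = 720) {
  stopifnot(inclination_deg >= 0, inclination_deg <= 90)
  a <- inclination_deg * pi / 180
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  use_pinhole <- !is.null(cal) && is.finite(cal$focal_length_px)
  ratio <- if (!use_pinhole) {
    # orthographic: segment direction (cos a * cos th, sin a, cos a * sin th),
    # image plane = (x, y); projected length of a unit segment
    sqrt(cos(a)^2 * cos(theta)^2 + sin(a)^2)
  } else {
    D <- cal$axis_distance_mm
    f <- cal$focal_length_px
    # unit segment centred on the axis; endpoints at +-0.5 along direction
    dx <- 0.5 * cos(a) * cos(theta)
    dy <- 0.5 * sin(a)
    dz <- 0.5 * cos(a) * sin(theta)   # depth toward the camera
    px1 <- f * dx / (D - dz); py1 <- f * dy / (D - dz)
    px2 <- f * -dx / (D + dz); py2 <- f * -dy / (D + dz)
    sqrt((px1 - px2)^2 + (py1 - py2)^2) / (f / D)
  }
  r <- if (rotation_average) mean(ratio) else min(ratio)
  100 * (1 - r)
}
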