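#' Parameters of one ridge-detection pass
#'
#' The detector follows Steger's scheme for curvilinear structures: the image
#' is smoothed with Gaussian-derivative filters at scale `sigma`, centerline
#' points are located where the first directional derivative (along the
#' Hessian's principal direction) has a sub-pixel zero and the magnitude of
#' the second directional derivative is large, and widths come from gradient
#' maxima perpendicular to the line.
#'
#' @param w maximum root half-width targeted by this pass (px, > 0).
#' @param sigma Gaussian scale (px); should satisfy `sigma >= w/3`
#'   (a warning is issued otherwise). Default `max(w/3, 1)`.
#' @param h expected gray-value contrast between root and (masked)
#'   background.
#' @param lower_ratio ratio `l/u` of the hysteresis thresholds, in `(0, 1]`;
#'   machine-vision practice suggests 0.25-0.5.
#' @param upper_u optional explicit upper threshold; by default computed from
#'   `w`, `sigma`, `h` via [ridge_threshold_u()].
#' @return An object of class `ridge_params`.
#' @export
ridge_params <- function(w, sigma = max(w / 3, 1), h = 25,
                         lower_ratio = 0.35, upper_u = NULL) {
  stopifnot(w > 0, sigma > 0, h > 0, lower_ratio > 0, lower_ratio <= 1)
  if (sigma < w / 3 - 1e-9) {
    warning(sprintf("sigma = %.3g violates sigma >= w/3 = %.3g", sigma, w / 3))
  }
  if (is.null(upper_u)) upper_u <- ridge_threshold_u(w, sigma, h)
  structure(
    list(w = w, sigma = sigma, h = h, lower_ratio = lower_ratio,
         upper_u = upper_u),
    class = "ridge_params"
  )
}

#' @export
print.ridge_params <- function(x, ...) {
  cat(sprintf(
    "<ridge_params> w = %.3g px, sigma = %.3g, h = %.3g, u = %.4g, l/u = %.2f\n",
    x$w, x$sigma, x$h, x$upper_u, x$lower_ratio))
  invisible(x)
}

#' Upper hysteresis threshold for ridge saliency
#'
#' Expected magnitude of the second-derivative response at the center of a
#' bar-shaped profile of half-width `w` and contrast `h` after smoothing at
#' scale `sigma`:
#' `u = 2 w h / (sqrt(2 pi) sigma^3) * exp(-w^2 / (2 sigma^2))`.
#'
#' @param w root half-width (px, > 0).
#' @param sigma Gaussian scale (> 0).
#' @param h root/background contrast (>= 0).
#' @return The threshold `u` (scalar).
#' @export
ridge_threshold_u <- function(w, sigma, h) {
  if (any(c(w, sigma) <= 0) || any(h < 0)) {
    stop("w and sigma must be positive, h non-negative")
  }
  2 * w * h / (sqrt(2 * pi) * sigma^3) * exp(-w^2 / (2 * sigma^2))
}

#' Discrete Gaussian kernel set
#'
#' Sampled Gaussian and first/second derivative kernels at scale `sigma`,
#' truncated at radius `ceil(3.5 sigma)` and calibrated so that responses to
#' constant, linear and quadratic signals are exact (`g0` sums to 1, `g1` and
#' `g2` sum to 0).
#'
#' @param sigma Gaussian scale (> 0).
#' @return List with `g0`, `g1`, `g2` and `radius`.
#' @export
gaussian_kernels <- function(sigma) {
  stopifnot(sigma > 0)
  .cpp_gauss_kernels(sigma)
}

#' Detect ridge lines in a gray image
#'
#' Bright-line polarity is assumed: the background must already be masked to
#' zero so roots are the bright structures. Candidate pixels have a principal
#' second-directional-derivative magnitude of at least `l = lower_ratio * u`
#' and a sub-pixel zero of the first directional derivative within the pixel;
#' points with response `>= u` seed lines, candidates down to `l` extend them
#' along the line direction (hysteresis linking). Linking splits at
#' collisions with already-linked points, so every line is a simple path.
#'
#' @param gray numeric matrix, background-masked gray image.
#' @param params a [ridge_params()].
#' @param exclusion optional binary matrix; pixels with value 1 cannot become
#'   line points (the deletion mask of the iterative scheme).
#' @return List of class `ridge_lines`: each element a matrix with columns
#'   `row, col, subr, subc, nx, ny, response`; the Gaussian derivative stack
#'   is attached as attribute `derivs` for reuse by [measure_widths()].
#' @export
detect_ridges <- function(gray, params, exclusion = NULL) {
  stopifnot(inherits(params, "ridge_params"))
  if (length(gray) == 0) return(structure(list(), class = "ridge_lines"))
  d <- .cpp_gauss_derivs(gray, params$sigma)
  excl <- if (is.null(exclusion)) matrix(0L, 0, 0) else {
    storage.mode(exclusion) <- "integer"
    exclusion
  }
  u <- params$upper_u
  lines <- .cpp_detect_ridges(d$rx, d$ry, d$rxx, d$rxy, d$ryy,
                              u, params$lower_ratio * u, excl)
  structure(lines, class = "ridge_lines", derivs = d, params = params)
}

#' Measure per-point line widths
#'
#' For every line point, the distances to the first local maximum of the
#' absolute gradient along both sides of the normal are measured (search
#' length `2.5 sigma`); a missing edge on one side is filled in by linear
#' interpolation from the nearest points of the same line that do have that
#' edge, and flagged. Points whose missing side cannot be interpolated from
#' anywhere on the line are dropped.
#'
#' @param lines result of [detect_ridges()].
#' @param gray the same gray image (used only if the derivative stack is not
#'   cached on `lines`).
#' @param params the [ridge_params()] of the detection pass.
#' @return Data frame with one row per surviving line point: `line_id, row,
#'   col, subr, subc, normal_angle, response, edge_left, edge_right,
#'   width_px, interpolated`.
#' @export
measure_widths <- function(lines, gray = NULL, params = attr(lines, "params")) {
  d <- attr(lines, "derivs")
  if (is.null(d)) {
    stopifnot(!is.null(gray))
    d <- .cpp_gauss_derivs(gray, params$sigma)
  }
  # the pass targets half-widths up to w, so edges can lie near distance w;
  # 2.5*sigma alone is shorter than w under the sigma >= w/3 scale rule
  max_dist <- max(2.5 * params$sigma, params$w + 2 * params$sigma)
  min_grad <- 0.1 * params$h / (sqrt(2 * pi) * params$sigma)
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    ln <- lines[[li]]
    # 1-px sampling with parabolic peak refinement; finer steps on the
    # bilinearly interpolated gradient produce flat plateaus whose first
    # sample fires the local-max test too early
    e <- .cpp_line_edges(ln, d$rx, d$ry, d$r, max_dist, min_grad, 1.0)
    # edge-pair quality: a centerline point sits roughly midway between its
    # edges (badly unbalanced pairs are off-center responses hugging one
    # boundary of a wider structure), at a gradient minimum between them
    # (spurious responses running alongside a boundary carry edge-strength
    # gradients themselves), and at least as bright as its edge positions
    # (rim responses on the shaded shoulder of a wide root are darker).
    emax <- pmax(e[, 3], e[, 4], na.rm = TRUE)
    emax[is.na(emax)] <- Inf
    bmax <- pmax(e[, 7], e[, 8], na.rm = TRUE)
    bmax[is.na(bmax)] <- -Inf
    bad <- abs(e[, 1] - e[, 2]) > pmax(2, 0.35 * (e[, 1] + e[, 2]))
    bad[is.na(bad)] <- FALSE
    bad <- bad | e[, 5] > 0.5 * emax | e[, 6] < bmax - 2
    # corrupted edge pairs (typically where another root crosses this one)
    # count as missing and are interpolated from intact neighbours on the
    # same line; lines with no intact point at all are discarded entirely
    eL <- e[, 1]; eR <- e[, 2]
    eL[bad] <- NA; eR[bad] <- NA
    el <- fill_missing_edges(eL)
    er <- fill_missing_edges(eR)
    interp <- (is.na(eL) & !is.na(el$x)) | (is.na(eR) & !is.na(er$x))
    keep <- !is.na(el$x) & !is.na(er$x)
    if (!any(keep)) next
    out[[li]] <- data.frame(
      line_id = li,
      row = ln[keep, 1], col = ln[keep, 2],
      subr = ln[keep, 3], subc = ln[keep, 4],
      normal_angle = atan2(ln[keep, 6], ln[keep, 5]),
      response = ln[keep, 7],
      edge_left = el$x[keep], edge_right = er$x[keep],
      width_px = el$x[keep] + er$x[keep],
      interpolated = interp[keep]
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(line_id = integer(), row = numeric(), col = numeric(),
                      subr = numeric(), subc = numeric(),
                      normal_angle = numeric(), response = numeric(),
                      edge_left = numeric(), edge_right = numeric(),
                      width_px = numeric(), interpolated = logical()))
  }
  do.call(rbind, out)
}

# linear interpolation of interior NA runs from the flanking values on the
# line; at the line ends, constant extrapolation over at most `max_ext`
# points. Farther positions stay NA (nothing local to interpolate from).
fill_missing_edges <- function(x, max_ext = 3L) {
  if (!anyNA(x)) return(list(x = x))
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(list(x = x))
  out <- x
  if (length(ok) >= 2L) {
    interior <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 1)$y
    out[is.na(out)] <- interior[is.na(out)]
  }
  first <- ok[1]; last <- ok[length(ok)]
  if (first > 1L) {
    lo <- max(1L, first - max_ext)
    out[lo:(first - 1L)] <- x[first]
  }
  if (last < length(x)) {
    hi <- min(length(x), last + max_ext)
    out[(last + 1L):hi] <- x[last]
  }
  list(x = out)
}
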