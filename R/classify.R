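#' Diameter class scheme
#'
#' The four cassava diameter classes: class 1 `< 2 mm` (fibrous), class 2
#' `2-6 mm` (transition), class 3 `6-20 mm` (early storage), class 4
#' `> 20 mm` (storage). Class intervals are half-open `[lo, hi)` with the
#' lower bound inclusive, so a width of exactly 2 mm falls in class 2.
#'
#' @param boundaries_mm strictly increasing positive boundaries between
#'   classes; `n_classes = length(boundaries_mm) + 1`.
#' @return An object of class `diameter_class_scheme`.
#' @export
diameter_classes <- function(boundaries_mm = c(2, 6, 20)) {
  stopifnot(all(boundaries_mm > 0), !is.unsorted(boundaries_mm,
                                                 strictly = TRUE))
  structure(
    list(boundaries_mm = boundaries_mm,
         n_classes = length(boundaries_mm) + 1L),
    class = "diameter_class_scheme"
  )
}

#' Assign widths to diameter classes
#'
#' @param width_mm numeric vector of diameters in mm.
#' @param scheme a [diameter_classes()] scheme.
#' @return Integer class indices (1-based).
#' @export
width_class <- function(width_mm, scheme = diameter_classes()) {
  findInterval(width_mm, c(0, scheme$boundaries_mm),
               rightmost.closed = FALSE, left.open = FALSE)
}

#' Diameter distribution from a width map
#'
#' Every centerline pixel contributes its metric length
#' (`length_weight * mm_per_px`) to the class containing its local diameter.
#' A fine histogram of diameter probabilities (1-mm resolution, weighted by
#' constituent length) is computed alongside.
#'
#' @param width_map data frame with `width_px` and (optionally)
#'   `length_weight` columns, e.g. from [transfer_widths()] +
#'   [corrected_lengths()].
#' @param scheme a [diameter_classes()] scheme.
#' @param cal a [camera_calibration()] supplying `mm_per_px`.
#' @param provenance optional tag (frame / plant / week) carried along.
#' @return An object of class `diameter_distribution`: per-class constituent
#'   `length_mm`, `fraction_pct`, `total_length_mm`, `n_pixels` and a
#'   `fine_histogram` (data frame `diameter_mm`, `probability`). An empty
#'   width map yields an all-zero distribution with `fraction_pct` set to
#'   `NA` and `empty = TRUE`.
#' @export
classify_widths <- function(width_map, scheme = diameter_classes(),
                            cal = camera_calibration(),
                            provenance = NULL) {
  n_cl <- scheme$n_classes
  if (!nrow(width_map)) {
    return(structure(
      list(length_mm = rep(0, n_cl), fraction_pct = rep(NA_real_, n_cl),
           total_length_mm = 0, n_pixels = 0L, empty = TRUE,
           fine_histogram = data.frame(diameter_mm = numeric(),
                                       probability = numeric()),
           scheme = scheme, provenance = provenance),
      class = "diameter_distribution"))
  }
  lw <- if (is.null(width_map$length_weight)) rep(1, nrow(width_map)) else
    width_map$length_weight
  width_mm <- px_to_mm(width_map$width_px, cal)
  len_mm <- lw * cal$mm_per_px
  cl <- width_class(width_mm, scheme)
  length_mm <- vapply(seq_len(n_cl), function(k) sum(len_mm[cl == k]),
                      numeric(1))
  total <- sum(length_mm)
  frac <- if (total > 0) 100 * length_mm / total else rep(NA_real_, n_cl)
  bin <- floor(width_mm)  # [k, k+1) mm
  tb <- tapply(len_mm, bin, sum)
  fine <- data.frame(diameter_mm = as.numeric(names(tb)) + 0.5,
                     probability = as.numeric(tb) / total)
  rownames(fine) <- NULL
  structure(
    list(length_mm = length_mm, fraction_pct = frac, total_length_mm = total,
         n_pixels = nrow(width_map), empty = FALSE, fine_histogram = fine,
         scheme = scheme, provenance = provenance),
    class = "diameter_distribution")
}

#' @export
print.diameter_distribution <- function(x, ...) {
  cat("<diameter_distribution>",
      if (!is.null(x$provenance)) paste0(" [", x$provenance, "]"), "\n",
      sep = "")
  b <- x$scheme$boundaries_mm
  labs <- c(sprintf("<%g", b[1]),
            if (length(b) > 1)
              sprintf("%g-%g", b[-length(b)], b[-1]),
            sprintf(">%g", b[length(b)]))
  for (k in seq_along(x$length_mm)) {
    cat(sprintf("  class %d (%s mm): %8.1f mm  %s\n", k, labs[k],
                x$length_mm[k],
                if (is.na(x$fraction_pct[k])) "" else
                  sprintf("%5.1f%%", x$fraction_pct[k])))
  }
  cat(sprintf("  total %8.1f mm over %d centerline px\n",
              x$total_length_mm, x$n_pixels))
  invisible(x)
}

#' Aggregate diameter distributions over frames
#'
#' `mean` (the multi-view default) averages the per-class percentage
#' fractions over frames, skipping frames with no detected roots; `max` and
#' `percentile` take the per-class maximum / p-th percentile of the absolute
#' class lengths over frames and renormalize the fractions.
#'
#' @param distributions non-empty list of `diameter_distribution` objects
#'   sharing one scheme.
#' @param mode `"mean"`, `"max"` or `"percentile"`.
#' @param p percentile in `[0, 100]` for `mode = "percentile"`.
#' @return A `diameter_distribution` with provenance `"aggregate"`; the
#'   number of used (non-empty) frames is in `$n_frames`.
#' @export
aggregate_frames <- function(distributions, mode = c("mean", "max",
                                                     "percentile"), p = 95) {
  mode <- match.arg(mode)
  if (!length(distributions)) stop("no distributions to aggregate")
  nonempty <- distributions[!vapply(distributions, function(d) d$empty,
                                    logical(1))]
  if (!length(nonempty)) stop("all frames are empty")
  scheme <- nonempty[[1]]$scheme
  lens <- do.call(rbind, lapply(nonempty, function(d) d$length_mm))
  if (mode == "mean") {
    fr <- do.call(rbind, lapply(nonempty, function(d) d$fraction_pct))
    frac <- colMeans(fr)
    length_mm <- colMeans(lens)
  } else {
    length_mm <- if (mode == "max") apply(lens, 2, max) else
      apply(lens, 2, stats::quantile, probs = p / 100, names = FALSE)
    frac <- if (sum(length_mm) > 0) 100 * length_mm / sum(length_mm) else
      rep(NA_real_, ncol(lens))
  }
  structure(
    list(length_mm = length_mm, fraction_pct = frac,
         total_length_mm = sum(length_mm),
         n_pixels = sum(vapply(nonempty, function(d) d$n_pixels, numeric(1))),
         empty = FALSE, fine_histogram = NULL, scheme = scheme,
         provenance = "aggregate", n_frames = length(nonempty),
         n_frames_dropped = length(distributions) - length(nonempty),
         mode = mode),
    class = "diameter_distribution")
}

#' Class growth dynamics over excavation weeks
#'
#' Box-plot statistics (median, quartiles, Tukey 1.5 IQR whiskers, outlier
#' count) of the per-class percentage fractions, per week, pooled over all
#' plants and frames of that week.
#'
#' @param per_week named list: week label -> list of
#'   `diameter_distribution` objects (one per plant/frame).
#' @return Data frame with columns `week, class, n, median, q1, q3,
#'   whisker_lo, whisker_hi, n_outliers`.
#' @export
growth_dynamics <- function(per_week) {
  stopifnot(length(per_week) >= 1)
  rows <- list()
  for (wk in names(per_week)) {
    ds <- per_week[[wk]]
    fr <- do.call(rbind, lapply(ds, function(d) d$fraction_pct))
    for (k in seq_len(ncol(fr))) {
      v <- fr[, k]
      v <- v[!is.na(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      lo <- min(v[v >= q[1] - 1.5 * iqr])
      hi <- max(v[v <= q[3] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <- data.frame(
        week = wk, class = k, n = length(v), median = q[2], q1 = q[1],
        q3 = q[3], whisker_lo = lo, whisker_hi = hi,
        n_outliers = sum(v < lo | v > hi))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
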