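#' Multi-scale iteration plan
#'
#' A single ridge-detection pass handles only a limited band of root
#' diameters: the scale rule `sigma >= w/3` means large roots need strong
#' smoothing, which erases thin roots. The iterative scheme runs a ladder of
#' passes with increasing (`forward`) or decreasing (`reverse`) target
#' half-widths `w`, protecting previously found centerlines with a growing
#' deletion mask so later passes extend rather than overwrite them.
#'
#' @param w_max largest target half-width (px, > `w_min`).
#' @param w_min smallest target half-width (px); 1.5 px is about the smallest
#'   resolvable root.
#' @param n_steps number of passes; three to four usually suffice. Default 3
#'   for `forward`, 4 for `reverse`.
#' @param direction `"forward"` (small to large) or `"reverse"`.
#' @param h expected root/background contrast, recycled over steps.
#' @param lower_ratio hysteresis ratio `l/u` for all steps.
#' @param gamma_factor deletion-kernel scale: after each pass, its centerline
#'   skeleton is dilated with a disc of diameter `gamma = gamma_factor * 2 w`
#'   and added to the deletion mask.
#' @param tau_min_px reverse mode only: per-step minimum accepted diameter
#'   (px). Default: the following (smaller) step's `w`, so each pass keeps
#'   only diameters of its own band; 0 for the last step.
#' @param sigma optional per-step Gaussian scales (recycled); default
#'   `max(w/3, 1)` per step. A conservative single-scale tuning would use
#'   `w/sqrt(3)` (the scale at which the response profile of a maximal-width
#'   root has a single central minimum).
#' @param min_width_px global minimum accepted diameter (px) across all
#'   steps; widths below ~3 px are not meaningfully measurable, so setting
#'   this to 3 suppresses sub-resolution structures (which otherwise appear
#'   one class too thick).
#' @return An object of class `iteration_plan` with a list of
#'   [ridge_params()] in `$steps`.
#' @export
iteration_plan <- function(w_max, w_min = 1.5,
                           n_steps = if (direction == "forward") 3L else 4L,
                           direction = c("forward", "reverse"), h = 25,
                           lower_ratio = 0.35, gamma_factor = 0.9,
                           tau_min_px = NULL, sigma = NULL,
                           min_width_px = 0) {
  direction <- match.arg(direction)
  stopifnot(w_max > w_min, w_min > 0, n_steps >= 1, gamma_factor > 0,
            gamma_factor <= 1)
  w <- if (n_steps == 1L) w_max else
    exp(seq(log(w_min), log(w_max), length.out = n_steps))
  if (direction == "reverse") w <- rev(w)
  h <- rep_len(h, n_steps)
  sigma <- if (is.null(sigma)) pmax(w / 3, 1) else rep_len(sigma, n_steps)
  steps <- lapply(seq_len(n_steps), function(i) {
    ridge_params(w = w[i], sigma = sigma[i], h = h[i],
                 lower_ratio = lower_ratio)
  })
  if (direction == "reverse" && is.null(tau_min_px)) {
    tau_min_px <- c(w[-1], 0)
  }
  if (direction == "forward") tau_min_px <- rep(0, n_steps)
  structure(
    list(steps = steps, direction = direction,
         tau_min_px = rep_len(tau_min_px, n_steps),
         gamma_factor = gamma_factor, min_width_px = min_width_px),
    class = "iteration_plan"
  )
}

#' @export
print.iteration_plan <- function(x, ...) {
  cat(sprintf("<iteration_plan> %s, %d steps\n", x$direction,
              length(x$steps)))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: w = %.3g, sigma = %.3g, h = %.3g, tau_min = %.3g\n",
                i, s$w, s$sigma, s$h, x$tau_min_px[i]))
  }
  invisible(x)
}

check_plan_order <- function(plan) {
  w <- vapply(plan$steps, function(s) s$w, numeric(1))
  if (plan$direction == "forward" && any(diff(w) <= 0)) {
    stop("forward plan requires strictly increasing w across steps")
  }
  if (plan$direction == "reverse" && any(diff(w) >= 0)) {
    stop("reverse plan requires strictly decreasing w across steps")
  }
  invisible(TRUE)
}

#' Run the iterative multi-scale ridge analysis
#'
#' Executes every pass of the plan on the background-masked gray image.
#' Pass `i` detects ridges outside the accumulated deletion mask `D_i`
#' (`D_1` empty), measures widths, optionally discards points below the
#' pass's minimum diameter (reverse mode), and then enlarges the deletion
#' mask by the dilated skeleton of its accepted centerlines
#' (`D_{i+1} = D_i | dilate(skeleton_i, disc(gamma_i / 2))`,
#' `gamma_i = gamma_factor * 2 w_i`). Accepted points accumulate into the
#' width map; a pixel claimed by an earlier pass is never overwritten.
#'
#' @param gray gray image, background already masked to zero (multiply by
#'   RS before calling, or pass `RS` and let the function do it).
#' @param RS binary root-system mask.
#' @param plan an [iteration_plan()].
#' @param D optional initial deletion mask (binary matrix).
#' @return An object of class `width_map_raw`: list with `width_map` (data
#'   frame `row, col, width_px, response, source_step`), `centerline` (binary
#'   matrix of raw centerline pixels) and `D` (final deletion mask).
#' @export
run_iterations <- function(gray, RS, plan, D = NULL) {
  stopifnot(inherits(plan, "iteration_plan"))
  check_plan_order(plan)
  gm <- gray * RS
  H <- nrow(gm); W <- ncol(gm)
  if (is.null(D)) D <- matrix(0L, H, W)
  storage.mode(D) <- "integer"
  claimed <- matrix(FALSE, H, W)
  recs <- list()
  centerline <- matrix(0L, H, W)
  dmap <- EBImage::distmap(RS)
  w_steps <- vapply(plan$steps, function(s) s$w, numeric(1))
  D_history <- vector("list", length(plan$steps))
  if (any(RS == 1L)) {
    for (i in seq_along(plan$steps)) {
      params <- plan$steps[[i]]
      D_history[[i]] <- D
      lines <- detect_ridges(gm, params, exclusion = D)
      wdf <- measure_widths(lines)
      if (nrow(wdf)) {
        if (plan$tau_min_px[i] > 0) {
          wdf <- wdf[wdf$width_px >= plan$tau_min_px[i], , drop = FALSE]
        }
        if (!is.null(plan$min_width_px) && plan$min_width_px > 0) {
          wdf <- wdf[wdf$width_px >= plan$min_width_px, , drop = FALSE]
        }
        # band tiling along the width axis: each pass keeps only diameters
        # of its own band. Without the upper cap, hysteresis linking creeps
        # along the centerline into thicker sections and claims them with
        # widths clipped at this pass's search range; without the lower
        # bound, later large-sigma passes re-detect already-claimed thin
        # roots a few px off-center (blur drift) as duplicates.
        if (plan$direction == "forward") {
          if (i < length(plan$steps)) {
            wdf <- wdf[wdf$width_px <= 1.9 * w_steps[i], , drop = FALSE]
          }
          if (i > 1L && nrow(wdf)) {
            wdf <- wdf[wdf$width_px > 1.85 * w_steps[i - 1L], , drop = FALSE]
          }
        }
        # the center of a structure of width W lies ~W/2 inside the
        # foreground; points hugging the mask boundary while claiming a
        # larger width are rasterization artifacts of the silhouette
        if (nrow(wdf)) {
          inside <- dmap[cbind(wdf$row, wdf$col)]
          wdf <- wdf[inside >= 0.3 * wdf$width_px, , drop = FALSE]
        }
      }
      if (nrow(wdf)) {
        # one record per integer pixel, highest response first
        wdf <- wdf[order(-wdf$response), , drop = FALSE]
        key <- (wdf$col - 1L) * H + wdf$row
        wdf <- wdf[!duplicated(key), , drop = FALSE]
        free <- !claimed[cbind(wdf$row, wdf$col)]
        wdf <- wdf[free, , drop = FALSE]
      }
      if (nrow(wdf)) {
        claimed[cbind(wdf$row, wdf$col)] <- TRUE
        recs[[length(recs) + 1L]] <- data.frame(
          row = wdf$row, col = wdf$col, width_px = wdf$width_px,
          response = wdf$response, source_step = i)
        centerline[cbind(wdf$row, wdf$col)] <- 1L
        # protective tube around each accepted centerline point, scaled by
        # the measured width: gamma = gamma_factor * width (never wider
        # than the detected root itself)
        D <- .cpp_paint_disks(D, as.integer(wdf$row), as.integer(wdf$col),
                              pmax(1, plan$gamma_factor * wdf$width_px / 2))
      }
    }
  }
  wm <- if (length(recs)) do.call(rbind, recs) else
    data.frame(row = integer(), col = integer(), width_px = numeric(),
               response = numeric(), source_step = integer())
  structure(list(width_map = wm, centerline = centerline, D = D,
                 D_history = D_history),
            class = "width_map_raw")
}

#' Postprocess raw centerlines
#'
#' Dilation by one pixel closes single-pixel gaps, thinning reduces all
#' centerlines to minimum (1-px) width, and masking with RS removes
#' centerline pixels that drifted into the background between parallel
#' roots.
#'
#' @param centerline binary matrix of raw centerline pixels.
#' @param RS binary root-system mask of the same shape.
#' @return Binary skeleton matrix.
#' @export
postprocess_centerlines <- function(centerline, RS) {
  stopifnot(all(dim(centerline) == dim(RS)))
  if (!any(centerline == 1L)) return(centerline * 0L)
  storage.mode(centerline) <- "integer"
  grown <- EBImage::dilate(centerline, EBImage::makeBrush(3L, "box"))
  grown <- matrix(as.integer(grown > 0), nrow(RS), ncol(RS))
  skel <- .cpp_thin(grown)
  matrix(as.integer(skel & RS), nrow(RS), ncol(RS))
}

#' Transfer raw width values onto skeleton pixels
#'
#' Each skeleton pixel takes the width of the nearest raw centerline pixel
#' within a 2-px radius; remaining pixels inherit the median width of their
#' 8-connected skeleton segment.
#'
#' @param skeleton binary skeleton matrix from [postprocess_centerlines()].
#' @param width_map_raw result of [run_iterations()].
#' @return Data frame `row, col, width_px, source_step` with one row per
#'   skeleton pixel (pixels in segments without any width information are
#'   dropped).
#' @export
transfer_widths <- function(skeleton, width_map_raw) {
  wm <- width_map_raw$width_map
  H <- nrow(skeleton); W <- ncol(skeleton)
  idx <- which(skeleton == 1L)
  if (!length(idx) || !nrow(wm)) {
    return(data.frame(row = integer(), col = integer(), width_px = numeric(),
                      source_step = integer()))
  }
  wimg <- matrix(NA_real_, H, W)
  simg <- matrix(NA_integer_, H, W)
  wimg[cbind(wm$row, wm$col)] <- wm$width_px
  simg[cbind(wm$row, wm$col)] <- wm$source_step
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  # offsets ordered by distance; first hit wins
  off <- expand.grid(dr = -2:2, dc = -2:2)
  off <- off[order(off$dr^2 + off$dc^2), ]
  wpx <- rep(NA_real_, length(idx))
  step <- rep(NA_integer_, length(idx))
  for (k in seq_len(nrow(off))) {
    need <- is.na(wpx)
    if (!any(need)) break
    rr <- rows[need] + off$dr[k]
    cc <- cols[need] + off$dc[k]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    val <- rep(NA_real_, sum(need))
    sv <- rep(NA_integer_, sum(need))
    val[ok] <- wimg[cbind(rr[ok], cc[ok])]
    sv[ok] <- simg[cbind(rr[ok], cc[ok])]
    wpx[need] <- val
    step[need] <- sv
  }
  if (anyNA(wpx)) {
    lab <- EBImage::bwlabel(skeleton)
    seg <- lab[cbind(rows, cols)]
    med <- tapply(wpx, seg, stats::median, na.rm = TRUE)
    fill <- is.na(wpx)
    wpx[fill] <- med[as.character(seg[fill])]
    step[fill] <- 0L
  }
  out <- data.frame(row = rows, col = cols, width_px = wpx,
                    source_step = step)
  out[!is.na(out$width_px), , drop = FALSE]
}

#' Dominant orientation per image tile
#'
#' The image is partitioned into `tile_size` x `tile_size` cells. Within
#' each cell a histogram of local skeleton orientations is built (the local
#' orientation of a skeleton pixel is the principal direction of the
#' skeleton pixels in its 7 x 7 neighbourhood); the dominant bin, refined by
#' the weighted mean angle of its members, gives the cell orientation
#' `omega_R`. The length-correction factor is `tau = 1 / cos(omega_R)` with
#' `omega_R` folded into `[0, pi/4]`, so `tau` ranges from 1 (axis-aligned)
#' to `sqrt(2)` (diagonal): a pixel step along a diagonal represents
#' `sqrt(2)` times the metric length of an axis-aligned step.
#'
#' @param skeleton binary skeleton matrix.
#' @param tile_size cell edge length in px.
#' @param n_bins number of orientation bins over `[0, pi)`.
#' @return Data frame of class `skeleton_segments`: `tile_row, tile_col,
#'   omega, tau_len, n_pixels`; empty cells emit no row.
#' @export
orientation_correction <- function(skeleton, tile_size = 32, n_bins = 9) {
  idx <- which(skeleton == 1L)
  if (!length(idx)) {
    return(structure(data.frame(tile_row = integer(), tile_col = integer(),
                                omega = numeric(), tau_len = numeric(),
                                n_pixels = integer()),
                     class = c("skeleton_segments", "data.frame")))
  }
  H <- nrow(skeleton)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  ang <- local_orientations(skeleton, rows, cols)
  tr <- (rows - 1L) %/% tile_size + 1L
  tc <- (cols - 1L) %/% tile_size + 1L
  tile <- paste(tr, tc, sep = "_")
  res <- lapply(split(seq_along(idx), tile), function(ii) {
    a <- ang[ii]
    a <- a[!is.na(a)]
    if (!length(a)) return(NULL)
    bin <- pmin(floor(a / (pi / n_bins)) + 1L, n_bins)
    dom <- as.integer(names(which.max(table(bin))))
    am <- a[bin == dom]
    # circular mean on doubled angles (orientations are pi-periodic)
    omega <- atan2(mean(sin(2 * am)), mean(cos(2 * am))) / 2
    if (omega < 0) omega <- omega + pi
    data.frame(tile_row = tr[ii][1], tile_col = tc[ii][1], omega = omega,
               tau_len = tau_from_omega(omega), n_pixels = length(ii))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(res) <- NULL
  structure(res, class = c("skeleton_segments", "data.frame"))
}

# fold an orientation into [0, pi/4] and return 1/cos
tau_from_omega <- function(omega) {
  a <- omega %% (pi / 2)
  a <- ifelse(a > pi / 4, pi / 2 - a, a)
  1 / cos(a)
}

# principal local direction of skeleton pixels in a (2r+1)^2 neighbourhood
local_orientations <- function(skeleton, rows, cols, r = 3L) {
  H <- nrow(skeleton); W <- ncol(skeleton)
  n <- length(rows)
  ang <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    r0 <- max(1L, rows[k] - r); r1 <- min(H, rows[k] + r)
    c0 <- max(1L, cols[k] - r); c1 <- min(W, cols[k] + r)
    sub <- skeleton[r0:r1, c0:c1, drop = FALSE]
    pts <- which(sub == 1L)
    if (length(pts) < 2L) next
    py <- ((pts - 1L) %% nrow(sub)) + 1L
    px <- ((pts - 1L) %/% nrow(sub)) + 1L
    py <- py - mean(py); px <- px - mean(px)
    sxx <- sum(px * px); syy <- sum(py * py); sxy <- sum(px * py)
    # orientation of the principal eigenvector of the scatter matrix
    theta <- 0.5 * atan2(2 * sxy, sxx - syy)
    ang[k] <- theta %% pi
  }
  ang
}

#' Attach metric length weights to a width map
#'
#' Every centerline pixel gets the length-correction factor `tau_len` of its
#' tile (pixels in tiles without an orientation estimate get weight 1), so
#' that the metric length of a path is `sum(tau_len) * mm_per_px` regardless
#' of its orientation. Uncorrected diagonal paths under-measure their length
#' by up to ~29% (`1 - 1/sqrt(2)`).
#'
#' @param width_map data frame with `row, col` columns (skeleton pixels).
#' @param segments result of [orientation_correction()].
#' @param tile_size the tile size used for `segments`.
#' @return `width_map` with an added `length_weight` column.
#' @export
corrected_lengths <- function(width_map, segments, tile_size = 32) {
  if (!nrow(width_map)) {
    width_map$length_weight <- numeric(0)
    return(width_map)
  }
  tr <- (width_map$row - 1L) %/% tile_size + 1L
  tc <- (width_map$col - 1L) %/% tile_size + 1L
  key <- paste(tr, tc, sep = "_")
  skey <- paste(segments$tile_row, segments$tile_col, sep = "_")
  tau <- segments$tau_len[match(key, skey)]
  tau[is.na(tau)] <- 1
  width_map$length_weight <- tau
  width_map
}
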