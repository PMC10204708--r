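#' Segmentation parameters
#'
#' Tunables for building the root-system mask RS from a frame. Mask
#' convention throughout: 1 = keep (root candidate), 0 = remove.
#'
#' @param T_beta normalized-blueness threshold in `[0, 255]`; pixels with
#'   normalized blueness below it count as foreground.
#' @param canny_low,canny_high hysteresis thresholds of the Canny edge
#'   detector used for the blur mask (gradient units on 0-255 images).
#' @param canny_sigma Gaussian scale of the Canny gradient (px).
#' @param blur_dilation_px dilation radius applied to Canny edges; pixels
#'   within this distance of a sharp edge are considered un-blurred.
#' @param theta_px erosion width applied to the combined mask (px, >= 0).
#' @param T_F minimum connected-component size kept (px, 8-connectivity).
#' @param stem_source `NULL` (no stem masking), a path to a binary PNG
#'   (nonzero = stem), or a function `(frame) -> binary matrix`.
#' @param label_regions list of numeric `c(x, y, w, h)` rectangles (0-based
#'   pixel coordinates, origin top-left) to blank out, e.g. QR-code labels.
#' @param use_blur_mask `FALSE` bypasses the blur mask (still images have no
#'   motion blur).
#' @param per_frame_norm normalize blueness by the per-frame maximum
#'   (`TRUE`, default) or by a caller-supplied maximum in `beta_max`.
#' @param beta_max optional fixed maximum for blueness normalization.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(T_beta = 128, canny_low = 50, canny_high = 150,
                                canny_sigma = 1.4, blur_dilation_px = 5,
                                theta_px = 0, T_F = 0, stem_source = NULL,
                                label_regions = list(), use_blur_mask = TRUE,
                                per_frame_norm = TRUE, beta_max = NULL) {
  stopifnot(T_beta >= 0, T_beta <= 255, canny_low < canny_high,
            blur_dilation_px >= 0, theta_px >= 0, T_F >= 0)
  structure(
    list(T_beta = T_beta, canny_low = canny_low, canny_high = canny_high,
         canny_sigma = canny_sigma, blur_dilation_px = blur_dilation_px,
         theta_px = theta_px, T_F = T_F, stem_source = stem_source,
         label_regions = label_regions, use_blur_mask = use_blur_mask,
         per_frame_norm = per_frame_norm, beta_max = beta_max),
    class = "segmentation_params"
  )
}

#' Blueness map of a frame
#'
#' The blueness index `beta = 3 B - 2.4 G - R` separates the blue imaging-box
#' background (large beta) from root material (small or negative beta).
#' `beta_norm` is `255 * beta / max(beta)`; when `max(beta) <= 0` (no blue
#' background present) the normalized map is defined as all zeros and a
#' warning is emitted, so that thresholding fails open to all-foreground.
#'
#' @param fr a [frame()].
#' @param beta_max optional externally fixed maximum (e.g. a per-video max).
#' @return List with `beta` (signed matrix) and `beta_norm` (in `[0, 255]`).
#' @export
blueness_map <- function(fr, beta_max = NULL) {
  stopifnot(inherits(fr, "root_frame"))
  p <- fr$pixels
  beta <- 3 * p[, , 3] - 2.4 * p[, , 2] - p[, , 1]
  mx <- if (is.null(beta_max)) max(beta) else beta_max
  if (mx <= 0) {
    warning("max blueness <= 0: no blue background; beta_norm set to 0 ",
            "(whole frame becomes foreground)")
    beta_norm <- array(0, dim(beta))
  } else {
    beta_norm <- pmax(pmin(255 * beta / mx, 255), 0)
    dim(beta_norm) <- dim(beta)
  }
  list(beta = beta, beta_norm = beta_norm)
}

#' Foreground mask from a blueness map
#'
#' @param bl result of [blueness_map()].
#' @param T_beta threshold; pixels with `beta_norm < T_beta` are foreground.
#' @return Binary matrix F (1 = foreground).
#' @export
segment_foreground <- function(bl, T_beta) {
  (bl$beta_norm < T_beta) * 1L
}

#' Canny edge detection
#'
#' Gaussian-derivative gradient, non-maximum suppression along the gradient
#' direction, and hysteresis thresholding (weak-edge components are kept only
#' when they touch a strong edge).
#'
#' @param gray numeric matrix (gray image, 0-255).
#' @param low,high hysteresis thresholds on the gradient magnitude.
#' @param sigma Gaussian scale in px.
#' @return Binary matrix of edge pixels.
#' @export
canny_edges <- function(gray, low = 50, high = 150, sigma = 1.4) {
  d <- .cpp_gauss_derivs(gray, sigma)
  gx <- d$rx
  gy <- d$ry
  mag <- sqrt(gx^2 + gy^2)
  H <- nrow(mag); W <- ncol(mag)
  # quantized gradient direction: 0 = horizontal gradient (vertical edge),
  # 1 = 45 deg, 2 = vertical, 3 = 135 deg
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (round(ang / (pi / 4)) %% 4)
  pad <- function(m) rbind(0, cbind(0, m, 0), 0)
  mp <- pad(mag)
  ci <- 2:(H + 1); cj <- 2:(W + 1)
  n_e  <- mp[ci, cj + 1]; n_w  <- mp[ci, cj - 1]
  n_s  <- mp[ci + 1, cj]; n_n  <- mp[ci - 1, cj]
  n_se <- mp[ci + 1, cj + 1]; n_nw <- mp[ci - 1, cj - 1]
  n_sw <- mp[ci + 1, cj - 1]; n_ne <- mp[ci - 1, cj + 1]
  nmax <- matrix(FALSE, H, W)
  s0 <- sector == 0; nmax[s0] <- mag[s0] >= n_e[s0]  & mag[s0] >= n_w[s0]
  s1 <- sector == 1; nmax[s1] <- mag[s1] >= n_se[s1] & mag[s1] >= n_nw[s1]
  s2 <- sector == 2; nmax[s2] <- mag[s2] >= n_s[s2]  & mag[s2] >= n_n[s2]
  s3 <- sector == 3; nmax[s3] <- mag[s3] >= n_sw[s3] & mag[s3] >= n_ne[s3]
  weak <- nmax & mag >= low
  strong <- nmax & mag >= high
  if (!any(strong)) return(matrix(0L, H, W))
  lab <- EBImage::bwlabel(weak * 1)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  edges <- matrix(0L, H, W)
  edges[lab %in% keep] <- 1L
  edges
}

#' Blur mask from sharp edges
#'
#' Motion-blurred roots lack discernible edges; everything farther than
#' `blur_dilation_px` from a Canny edge is flagged as blurred (or background)
#' with value 0. Sharp regions get value 1.
#'
#' @param gray gray image matrix.
#' @param params a [segmentation_params()].
#' @return Binary matrix C.
#' @export
blur_mask <- function(gray, params = segmentation_params()) {
  edges <- canny_edges(gray, params$canny_low, params$canny_high,
                       params$canny_sigma)
  if (!any(edges == 1L)) return(matrix(0L, nrow(gray), ncol(gray)))
  r <- params$blur_dilation_px
  if (r > 0) {
    k <- EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
    edges <- EBImage::dilate(edges, k)
  }
  matrix(as.integer(edges > 0), nrow(gray), ncol(gray))
}

#' Label mask for fixed exclusion regions
#'
#' @param shape `c(H, W)` of the frame.
#' @param label_regions list of `c(x, y, w, h)` rectangles in 0-based pixel
#'   coordinates, origin top-left; regions are clipped to the image.
#' @return Binary matrix L (0 inside the rectangles).
#' @export
label_mask <- function(shape, label_regions = list()) {
  L <- matrix(1L, shape[1], shape[2])
  for (rg in label_regions) {
    x0 <- max(0, floor(rg[1])); y0 <- max(0, floor(rg[2]))
    x1 <- min(shape[2], rg[1] + rg[3]); y1 <- min(shape[1], rg[2] + rg[4])
    if (x1 > x0 && y1 > y0) {
      L[(y0 + 1):y1, (x0 + 1):x1] <- 0L
    }
  }
  L
}

#' Stem mask
#'
#' The stem must not be mistaken for a thick root. An external stem
#' segmentation (file or plug-in function, 1 = stem) is inverted so that stem
#' pixels are 0. With `stem_source = NULL` the mask is all ones.
#'
#' @param fr a [frame()].
#' @param stem_source `NULL`, a binary PNG path, or a function
#'   `(frame) -> matrix`.
#' @return Binary matrix S (stem pixels 0).
#' @export
stem_mask <- function(fr, stem_source = NULL) {
  shape <- dim(fr$pixels)[1:2]
  if (is.null(stem_source)) return(matrix(1L, shape[1], shape[2]))
  stem <- if (is.function(stem_source)) {
    stem_source(fr)
  } else {
    img <- png::readPNG(stem_source)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }
  if (!all(dim(stem)[1:2] == shape)) {
    stop("stem mask shape ", paste(dim(stem), collapse = "x"),
         " does not match frame shape ", paste(shape, collapse = "x"))
  }
  if (!any(stem > 0)) warning("stem source returned an empty mask")
  matrix(as.integer(stem <= 0), shape[1], shape[2])
}

#' Combine the factor masks
#'
#' Pointwise logical AND: `M = F & S & L & C`.
#'
#' @param F,S,L,C binary matrices of identical shape.
#' @return Binary matrix M.
#' @export
combine_masks <- function(F, S, L, C) {
  dims <- list(dim(F), dim(S), dim(L), dim(C))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("mask shapes differ")
  }
  (F & S & L & C) * 1L
}

#' Refine the combined mask into the root-system mask RS
#'
#' Morphological erosion by a disc of radius `theta_px`, then removal of
#' 8-connected components smaller than `T_F` pixels (in that order).
#'
#' @param M binary matrix.
#' @param theta_px erosion radius (0 = no erosion).
#' @param T_F minimum fragment size in px (0 = keep all).
#' @return Binary matrix RS.
#' @export
refine_root_mask <- function(M, theta_px = 0, T_F = 0) {
  RS <- M
  if (theta_px > 0) {
    k <- EBImage::makeBrush(2L * as.integer(theta_px) + 1L, "disc")
    RS <- EBImage::erode(RS, k)
  }
  RS <- matrix(as.integer(RS > 0), nrow(M), ncol(M))
  if (T_F > 0 && any(RS == 1L)) {
    lab <- EBImage::bwlabel(RS)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < T_F)
    if (length(small)) RS[lab %in% small] <- 0L
  }
  RS
}

#' Segment the root system of a frame
#'
#' Full segmentation stage: foreground (blueness), stem, label and blur masks
#' are combined (`M = F & S & L & C`) and refined by erosion and fragment
#' filtering into the root-system mask RS.
#'
#' @param fr a [frame()].
#' @param params a [segmentation_params()].
#' @return An object of class `mask_set`: list of binary matrices
#'   `F, S, L, C, M, RS` plus the blueness map.
#' @export
segment_root_system <- function(fr, params = segmentation_params()) {
  bl <- blueness_map(fr, beta_max = if (isTRUE(params$per_frame_norm)) NULL
                     else params$beta_max)
  F <- segment_foreground(bl, params$T_beta)
  S <- stem_mask(fr, params$stem_source)
  L <- label_mask(dim(fr$pixels)[1:2], params$label_regions)
  C <- if (isTRUE(params$use_blur_mask)) {
    blur_mask(to_gray(fr), params)
  } else {
    matrix(1L, nrow(F), ncol(F))
  }
  M <- combine_masks(F, S, L, C)
  RS <- refine_root_mask(M, params$theta_px, params$T_F)
  structure(list(F = F, S = S, L = L, C = C, M = M, RS = RS, blueness = bl),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d x %d px; RS covers %d px (%.1f%%)\n",
              nrow(x$RS), ncol(x$RS), sum(x$RS),
              100 * mean(x$RS)))
  invisible(x)
}

#' Write the segmentation masks as PNG files
#'
#' @param masks a `mask_set`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_masks_png <- function(masks, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("F", "S", "L", "C", "M", "RS")
  paths <- vapply(nm, function(n) {
    p <- file.path(dir, sprintf("%s_%s.png", prefix, n))
    png::writePNG(masks[[n]], p)
    p
  }, character(1))
  invisible(paths)
}
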