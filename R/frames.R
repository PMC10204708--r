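#' Construct a frame
#'
#' A frame is one image of a (possibly rotating) excavated root system:
#' an H x W x 3 array of 8-bit intensities plus capture metadata.
#'
#' @param pixels numeric H x W x 3 array with values in `[0, 255]`, or an
#'   H x W matrix (replicated to three identical channels).
#' @param index integer frame index (>= 0), capture order.
#' @param angle_deg optional rotation angle of the root at capture (degrees).
#' @return An object of class `root_frame`.
#' @export
frame <- function(pixels, index = 0L, angle_deg = NA_real_) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stop("frame must have positive height and width")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("frame intensities must lie in [0, 255]")
  }
  structure(
    list(pixels = pixels, index = as.integer(index),
         angle_deg = as.numeric(angle_deg)),
    class = "root_frame"
  )
}

#' @export
print.root_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<root_frame> %d x %d px, index %d%s\n", d[1], d[2], x$index,
              if (is.na(x$angle_deg)) "" else
                sprintf(", angle %.1f deg", x$angle_deg)))
  invisible(x)
}

#' Camera calibration for the rotating-box setup
#'
#' Carries the metric scale at the rotation-axis plane. The default
#' camera-to-axis distance matches a turntable imaging box with the camera
#' mounted 113.5 cm from the rotation axis.
#'
#' @param mm_per_px millimetres per pixel at the rotation-axis plane (> 0).
#'   This value is setup-specific and must be measured by the user; the
#'   package-wide fixture default of 0.5 mm/px is arbitrary.
#' @param axis_distance_mm camera-to-rotation-axis distance in mm (> 0).
#' @param focal_length_px optional focal length in pixels, used by the
#'   perspective-shortening model when a full pinhole camera is wanted.
#' @return An object of class `camera_calibration`.
#' @export
camera_calibration <- function(mm_per_px = 0.5, axis_distance_mm = 1135,
                               focal_length_px = NA_real_) {
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1L, mm_per_px > 0,
            is.numeric(axis_distance_mm), axis_distance_mm > 0)
  structure(
    list(mm_per_px = mm_per_px, axis_distance_mm = axis_distance_mm,
         focal_length_px = as.numeric(focal_length_px)),
    class = "camera_calibration"
  )
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration> %.4g mm/px, axis distance %.4g mm\n",
              x$mm_per_px, x$axis_distance_mm))
  invisible(x)
}

#' Convert pixel widths or lengths to millimetres
#'
#' Linear scaling with the calibration's mm-per-pixel factor.
#'
#' @param width_px numeric vector of pixel measures (>= 0).
#' @param cal a [camera_calibration()].
#' @return Numeric vector in millimetres.
#' @export
px_to_mm <- function(width_px, cal) {
  stopifnot(inherits(cal, "camera_calibration"))
  if (any(width_px < 0, na.rm = TRUE)) stop("negative pixel width")
  width_px * cal$mm_per_px
}

#' Convert a frame to a gray-value image
#'
#' Standard Rec.601 luminance weighting (0.299 R + 0.587 G + 0.114 B). The
#' exact weighting is a calibration detail here: the ridge detector's contrast
#' parameter `h` is set by the user per iteration step, so any fixed convex
#' weighting works.
#'
#' @param fr a [frame()].
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
to_gray <- function(fr) {
  stopifnot(inherits(fr, "root_frame"))
  p <- fr$pixels
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

#' Describe an image sequence
#'
#' @param source path to a directory of TIF/PNG images (read in lexicographic
#'   order). Video files cannot be decoded in R; extract frames to images
#'   first (e.g. with ffmpeg) and point `source` at the directory.
#' @param angular_step_deg nominal rotation step between frames (degrees,
#'   > 0; a full-rotation video captured every ~2 degrees gives 180 frames).
#' @param n_frames expected frame count (`NA` to skip the check).
#' @param full_rotation if `TRUE`, frame angles are assigned as
#'   `index * angular_step_deg`.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(source, angular_step_deg = 2, n_frames = NA_integer_,
                          full_rotation = TRUE) {
  stopifnot(angular_step_deg > 0)
  structure(
    list(source = source, angular_step_deg = angular_step_deg,
         n_frames = as.integer(n_frames), full_rotation = full_rotation),
    class = "sequence_spec"
  )
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext,
         " (supported: png, tif; decode videos to frames externally)")
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE] * 255
}

#' Load an ordered image sequence as frames
#'
#' Reads all TIF/PNG files of a directory in lexicographic order (the capture
#' order convention of turntable acquisition software) and attaches rotation
#' angles when a full rotation is declared.
#'
#' @param spec a [sequence_spec()], or a directory path (then the defaults of
#'   `sequence_spec()` apply).
#' @return List of [frame()] objects with strictly increasing indices.
#' @export
load_frames <- function(spec) {
  if (is.character(spec)) spec <- sequence_spec(spec)
  stopifnot(inherits(spec, "sequence_spec"))
  src <- spec$source
  if (!dir.exists(src)) {
    if (file.exists(src)) {
      stop("'", src, "' is a file; video decoding is not available. ",
           "Extract frames to an image directory and pass that instead.")
    }
    stop("sequence source not found: ", src)
  }
  files <- sort(list.files(src, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no readable frames in ", src)
  if (!is.na(spec$n_frames) && length(files) != spec$n_frames) {
    warning(sprintf("expected %d frames, found %d", spec$n_frames,
                    length(files)))
  }
  lapply(seq_along(files), function(i) {
    px <- tryCatch(read_image_file(files[i]),
                   error = function(e) stop("frame ", i - 1L, " unreadable (",
                                            files[i], "): ",
                                            conditionMessage(e), call. = FALSE))
    frame(px, index = i - 1L,
          angle_deg = if (isTRUE(spec$full_rotation))
            (i - 1L) * spec$angular_step_deg else NA_real_)
  })
}

#' Read a flat configuration file
#'
#' YAML file with `camera` (axis_distance_mm, mm_per_px) and `sequence`
#' (angular_step_deg) sections; unknown keys are kept verbatim.
#'
#' @param path path to a YAML config file.
#' @return Named list with a `camera_calibration` under `$camera`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cam <- cfg$camera
  cfg$camera <- camera_calibration(
    mm_per_px = if (!is.null(cam$mm_per_px)) cam$mm_per_px else 0.5,
    axis_distance_mm = if (!is.null(cam$axis_distance_mm))
      cam$axis_distance_mm else 1135
  )
  cfg
}
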