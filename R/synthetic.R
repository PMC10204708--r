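#' @name synthetic
#' @title Synthetic root scenes with analytic ground truth
#' @description
#' The validation data are 2D-rendered root systems in front of a blue
#' background, front-lit so roots appear rounded. Each root is a tapered
#' tube around a smooth planar axis; its per-diameter-bin constituent length
#' (the ground truth) is computed analytically from the piecewise-linear
#' radius profile, never from pixels, so the truth table is exact and
#' independent of the rendering resolution.
NULL

# fine ground-truth diameter bins (mm): 0-1, 1-2, ..., 9-10, 10-15, 15-20,
# 20-25, 25-30, 30+
fine_bin_edges <- function() c(0:10, 15, 20, 25, 30, Inf)

fine_bin_labels <- function() {
  e <- fine_bin_edges()
  n <- length(e) - 1L
  c(sprintf("%g-%g", e[seq_len(n - 1)], e[seq_len(n - 1) + 1]), "30+")
}

# per-type maximum-diameter and length ranges (mm)
type_diameter_range <- function(root_type) {
  switch(root_type,
         I = c(1.0, 1.8), II = c(2.8, 5.5), III = c(7, 18), IV = c(22, 45),
         stop("unknown root type: ", root_type))
}

type_length_range <- function(root_type) {
  switch(root_type,
         I = c(60, 140), II = c(200, 400), III = c(250, 450),
         IV = c(250, 500), stop("unknown root type: ", root_type))
}

# default rendering resolution per type for single-root scenes (mm/px),
# chosen so a type's thinnest class stays comfortably above 3 px
type_mm_per_px <- function(root_type) {
  switch(root_type, I = 0.15, II = 0.25, III = 0.4, IV = 0.6)
}

#' Specify a synthetic root
#'
#' @param root_type `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param axis n x 2 matrix of planar axis coordinates in mm (columns x, y;
#'   y grows downward), a polyline of gentle curvature.
#' @param radius_knots data frame / matrix with columns `s` (arc length from
#'   the base, mm) and `d` (local diameter, mm): the piecewise-linear
#'   diameter profile, tapering toward the tip.
#' @param max_diameter_mm maximum diameter (must respect the type bound and
#'   the global 45 mm cap).
#' @return An object of class `root_spec`.
#' @export
root_spec <- function(root_type, axis, radius_knots, max_diameter_mm) {
  bounds <- type_diameter_range(root_type)
  if (max_diameter_mm > 45 + 1e-9) stop("maximum diameter exceeds 45 mm cap")
  lo <- c(I = 0, II = 2, III = 6, IV = 20)[[root_type]]
  hi <- c(I = 2, II = 6, III = 20, IV = 45)[[root_type]]
  if (max_diameter_mm < lo || max_diameter_mm > hi) {
    stop(sprintf("type %s root must have max diameter in (%g, %g] mm",
                 root_type, lo, hi))
  }
  radius_knots <- as.data.frame(radius_knots)
  stopifnot(all(c("s", "d") %in% names(radius_knots)),
            all(radius_knots$d >= 0), nrow(radius_knots) >= 2,
            !is.unsorted(radius_knots$s, strictly = TRUE))
  structure(
    list(root_type = root_type, axis = axis, radius_knots = radius_knots,
         max_diameter_mm = max_diameter_mm),
    class = "root_spec"
  )
}

#' Analytic ground truth of a root
#'
#' Arc length per fine diameter bin, computed exactly from the
#' piecewise-linear diameter profile, plus the merge into classes 1-4.
#'
#' @param root a [root_spec()] (or a list of them, summed).
#' @param scheme a [diameter_classes()] scheme for the merged table.
#' @return An object of class `ground_truth`: list with `fine` (named vector
#'   of lengths per fine bin, mm), `class_mm` (length per class 1..4) and
#'   `total_mm`.
#' @export
root_truth <- function(root, scheme = diameter_classes()) {
  if (inherits(root, "root_spec")) root <- list(root)
  edges <- fine_bin_edges()
  fine <- numeric(length(edges) - 1L)
  for (r in root) {
    k <- r$radius_knots
    for (i in seq_len(nrow(k) - 1L)) {
      s1 <- k$s[i]; s2 <- k$s[i + 1]
      d1 <- k$d[i]; d2 <- k$d[i + 1]
      seg <- s2 - s1
      if (seg <= 0) next
      dlo <- min(d1, d2); dhi <- max(d1, d2)
      for (b in seq_len(length(edges) - 1L)) {
        a <- edges[b]; bb <- edges[b + 1]
        if (dhi == dlo) {
          if (dlo >= a && dlo < bb) fine[b] <- fine[b] + seg
        } else {
          ov <- max(0, min(dhi, bb) - max(dlo, a))
          fine[b] <- fine[b] + seg * ov / (dhi - dlo)
        }
      }
    }
  }
  names(fine) <- fine_bin_labels()
  class_edges <- c(0, scheme$boundaries_mm, Inf)
  cls <- numeric(scheme$n_classes)
  for (b in seq_len(length(edges) - 1L)) {
    k <- findInterval(edges[b], class_edges)
    cls[k] <- cls[k] + fine[b]
  }
  structure(list(fine = fine, class_mm = cls, total_mm = sum(fine)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> total", round(x$total_mm, 1), "mm; classes 1-4 [mm]:",
      paste(round(x$class_mm, 1), collapse = ", "), "\n")
  invisible(x)
}

# random axis polyline: persistent random heading walk with gravitropic pull
# toward vertical, spline-smoothed and densely resampled so the rendered
# tube is free of rasterization scallops at bends. Returns an n x 2 matrix
# in mm, anchored at (0, 0), y downward.
make_axis <- function(length_mm, emergence_deg, ds = 2, wobble_deg = 5,
                      pull = 0.004, ds_fine = 0.5) {
  n <- max(2L, ceiling(length_mm / ds) + 1L)
  theta <- numeric(n - 1L)
  theta[1] <- emergence_deg * pi / 180
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      theta[k] <- theta[k - 1] + stats::rnorm(1, 0, wobble_deg * pi / 180) -
        pull * theta[k - 1]
    }
  }
  steps <- c(rep(ds, n - 2L), length_mm - (n - 2L) * ds)
  steps[steps <= 0] <- ds / 10
  x <- c(0, cumsum(steps * sin(theta)))
  y <- c(0, cumsum(steps * cos(theta)))
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  m <- max(2L, ceiling(s[length(s)] / ds_fine) + 1L)
  sf <- seq(0, s[length(s)], length.out = m)
  cbind(x = stats::spline(s, x, xout = sf)$y,
        y = stats::spline(s, y, xout = sf)$y)
}

# exact arc length of a polyline
axis_length <- function(axis) {
  sum(sqrt(diff(axis[, 1])^2 + diff(axis[, 2])^2))
}

# piecewise-linear diameter profile. Fibrous/transition roots taper from
# the base; storage-type roots (d_max above the early-storage bound) have a
# narrower proximal neck, swell to their maximum in the first half and then
# taper - the typical excavated storage-root shape.
make_profile <- function(length_mm, d_max, d_tip = 0.4, shoulder = 0.3) {
  d_tip <- min(d_tip, d_max)
  if (d_max <= 6) {
    d_mid <- max(0.92 * d_max, d_tip)
    return(data.frame(s = c(0, shoulder * length_mm, length_mm),
                      d = c(d_max, d_mid, d_tip)))
  }
  d_neck <- max(0.35 * d_max, d_tip)
  data.frame(s = c(0, 0.15, 0.55, 1) * length_mm,
             d = c(d_neck, d_max, max(0.9 * d_max, d_tip), d_tip))
}

# one random root of a given type; all randomness from the current RNG stream
make_random_root <- function(root_type, emergence_deg = NULL, d_tip = 0.4,
                             length_mm = NULL, d_max = NULL) {
  dr <- type_diameter_range(root_type)
  lr <- type_length_range(root_type)
  if (is.null(d_max)) d_max <- stats::runif(1, dr[1], dr[2])
  if (is.null(length_mm)) length_mm <- stats::runif(1, lr[1], lr[2])
  if (is.null(emergence_deg)) emergence_deg <- stats::runif(1, -45, 45)
  axis <- make_axis(length_mm, emergence_deg)
  # the profile (and hence the analytic truth) lives on the exact arc
  # length of the rendered polyline
  root_spec(root_type, axis,
            make_profile(axis_length(axis), d_max, d_tip = d_tip), d_max)
}

# render a list of root_spec objects; canvas auto-sized unless given.
# Returns a root_frame. Colours/shading emulate a front-lit root on a blue
# imaging-box wall.
render_root_scene <- function(roots, mm_per_px, canvas = NULL, margin_px = 12,
                              shading = TRUE, bg = c(35, 55, 190),
                              base_col = c(205, 192, 175), col_jitter = 8) {
  polys <- lapply(roots, function(r) {
    k <- r$radius_knots
    s_axis <- c(0, cumsum(sqrt(diff(r$axis[, 1])^2 + diff(r$axis[, 2])^2)))
    d_axis <- stats::approx(k$s, k$d, xout = pmin(s_axis, max(k$s)),
                            rule = 2)$y
    list(x = r$axis[, 1] / mm_per_px, y = r$axis[, 2] / mm_per_px,
         r = d_axis / 2 / mm_per_px)
  })
  all_x <- unlist(lapply(polys, function(p) c(p$x - p$r, p$x + p$r)))
  all_y <- unlist(lapply(polys, function(p) c(p$y - p$r, p$y + p$r)))
  if (is.null(canvas)) {
    W <- ceiling(diff(range(all_x))) + 2 * margin_px
    H <- ceiling(diff(range(all_y))) + 2 * margin_px
    x0 <- margin_px - min(all_x)
    y0 <- margin_px - min(all_y)
  } else {
    H <- canvas[1]; W <- canvas[2]
    x0 <- canvas[3]; y0 <- canvas[4]
    if (min(all_x) + x0 < 0 || max(all_x) + x0 > W ||
        min(all_y) + y0 < 0 || max(all_y) + y0 > H) {
      stop("root system exceeds the given canvas")
    }
  }
  rlist <- lapply(polys, function(p) {
    jit <- stats::runif(3, -col_jitter, col_jitter)
    list(x = p$x + x0 + 1, y = p$y + y0 + 1, r = p$r,
         col = pmin(pmax(base_col + jit, 0), 255),
         shade_axis = 1.0, shade_edge = if (shading) 0.62 else 1.0)
  })
  px <- .cpp_render_scene(as.integer(H), as.integer(W), bg, rlist)
  frame(px)
}

#' Generate a single synthetic root image with ground truth
#'
#' One randomly drawn root of the requested type, rendered on a blue
#' background with front-lit shading. The per-type default resolution keeps
#' the thinnest rendered diameter at `min_tip_px` pixels (a resolution floor
#' below which widths are not meaningfully measurable).
#'
#' @param root_type `"I"` to `"IV"`.
#' @param mm_per_px resolution; `NULL` picks the per-type default
#'   (I: 0.15, II: 0.25, III: 0.4, IV: 0.6 mm/px).
#' @param seed integer seed; the same seed reproduces the scene bit for bit.
#' @param min_tip_px minimum rendered tip diameter in px (the radius profile
#'   is truncated there); must be >= 1.
#' @param shading render the radial front-light shading.
#' @return An object of class `root_scene`: list with `frame`
#'   (a [frame()]), `truth` (a [root_truth()]), `roots` (list of
#'   [root_spec()]), `mm_per_px` and `seed`.
#' @export
generate_single_root <- function(root_type, mm_per_px = NULL, seed = 1L,
                                 min_tip_px = 3, shading = TRUE) {
  if (is.null(mm_per_px)) mm_per_px <- type_mm_per_px(root_type)
  stopifnot(min_tip_px >= 1)
  set.seed(seed)
  root <- make_random_root(root_type, emergence_deg = stats::runif(1, -35, 35),
                           d_tip = min_tip_px * mm_per_px)
  fr <- render_root_scene(list(root), mm_per_px, shading = shading)
  structure(
    list(frame = fr, truth = root_truth(root), roots = list(root),
         mm_per_px = mm_per_px, seed = seed),
    class = "root_scene"
  )
}

#' @export
print.root_scene <- function(x, ...) {
  d <- dim(x$frame$pixels)
  cat(sprintf("<root_scene> %d root(s), %d x %d px at %.3g mm/px\n",
              length(x$roots), d[1], d[2], x$mm_per_px))
  print(x$truth)
  invisible(x)
}

#' Generate a synthetic root system with a common basal anchor
#'
#' Roots emerge from a small anchor region with randomized emergence angles;
#' self-occlusion between roots is allowed (later-drawn roots paint over
#' earlier ones), as in clustered excavated root crowns. The scene ground
#' truth is the sum of the per-root analytic truths.
#'
#' @param n_roots number of roots (>= 1).
#' @param type_mix a single type (`"III"`) or a named vector of type counts
#'   (`c(II = 3, III = 5)`), which must sum to `n_roots`.
#' @param mm_per_px resolution (default 0.6 mm/px, the video-box level where
#'   class-1 diameters are at most ~2 px).
#' @param seed integer seed.
#' @param d_tip tip diameter in mm at which the taper is truncated.
#' @param shading render shading.
#' @return A `root_scene` (see [generate_single_root()]).
#' @export
generate_root_system <- function(n_roots, type_mix, mm_per_px = 0.6,
                                 seed = 1L, d_tip = 0.4, shading = TRUE) {
  stopifnot(n_roots >= 1)
  types <- if (length(type_mix) == 1L && is.null(names(type_mix))) {
    rep(type_mix, n_roots)
  } else {
    stopifnot(sum(type_mix) == n_roots)
    rep(names(type_mix), times = type_mix)
  }
  set.seed(seed)
  anchors <- cbind(stats::runif(n_roots, -15, 15), stats::runif(n_roots, 0, 6))
  # roots leave the anchor in angular order (the quasi-2D growth volume
  # leaves no room for roots to cross in depth, so a crown fans out)
  angles <- seq(-45, 45, length.out = n_roots)[sample(n_roots)] +
    stats::rnorm(n_roots, 0, 3)
  roots <- lapply(seq_len(n_roots), function(i) {
    r <- make_random_root(types[i], emergence_deg = angles[i], d_tip = d_tip)
    r$axis[, 1] <- r$axis[, 1] + anchors[i, 1]
    r$axis[, 2] <- r$axis[, 2] + anchors[i, 2]
    r
  })
  fr <- render_root_scene(roots, mm_per_px, shading = shading)
  structure(
    list(frame = fr, truth = root_truth(roots), roots = roots,
         mm_per_px = mm_per_px, seed = seed),
    class = "root_scene"
  )
}

# --- time series -----------------------------------------------------------

# destiny-specific diameter trajectory d(t); storage roots cross the 20 mm
# class boundary at `class4_week` by construction
diameter_at_week <- function(traj, t) {
  with(traj, {
    if (t < emergence) return(0)
    switch(destiny,
      I = min(d_target, 1.0 + 0.15 * (t - emergence)),
      II = 1.2 + (d_target - 1.2) * min(max((t - thicken_week) / 3, 0), 1),
      III = 1.2 + (d_target - 1.2) * min(max((t - thicken_week) / 4, 0), 1),
      IV = {
        xs <- c(thicken_week, class4_week, 13)
        ys <- c(1.2, 20 + d_cross, d_target)
        if (t <= xs[1]) 1.2 else stats::approx(xs, ys, xout = min(t, 13),
                                               rule = 2)$y
      })
  })
}

length_at_week <- function(traj, t) {
  if (t < traj$emergence) return(0)
  traj$length_max * min(1, (t - traj$emergence + 1) / traj$grow_weeks)
}

#' Simulate a weekly time series of growing root systems
#'
#' Emulates secondary thickening of a storage-root crop: an 80-root master
#' system grows from week 2 (only short fibrous roots) to week 13 (fully
#' developed storage roots). Each root follows a fixed planar axis that
#' elongates over time while its diameter profile thickens according to its
#' destiny type (44 stay fibrous, 16 become transition roots, 12 early
#' storage, 8 storage by default). Storage-root diameters cross the 20 mm
#' class-4 boundary at `class4_week`, so earlier weeks have exactly zero
#' class-4 truth. Each week, `n_subsets` scenes are formed by stratified
#' sampling of `subset_size` roots such that the current root-type
#' proportions of the full system are preserved within one root per type.
#'
#' Scenes are rendered on demand with [render_series_scene()] to keep memory
#' bounded; this function returns the dataset plan with all truths.
#'
#' @param weeks integer vector of weeks (default 2:13).
#' @param n_roots master-system size.
#' @param n_subsets scenes per week.
#' @param subset_size roots per scene.
#' @param mm_per_px rendering resolution (video-box level).
#' @param seed integer seed determining everything.
#' @param destiny_counts named counts of destiny types, summing to `n_roots`.
#' @param class4_week first week with nonzero class-4 truth.
#' @return An object of class `root_series`: list with `trajectories`,
#'   `scenes` (data frame week/subset), `subsets` (list of root index
#'   vectors), `truths` (list of [root_truth()] per scene), `canvas`,
#'   `mm_per_px`, `weeks`.
#' @export
generate_time_series <- function(weeks = 2:13, n_roots = 80, n_subsets = 25,
                                 subset_size = 17, mm_per_px = 0.6, seed = 1L,
                                 destiny_counts = c(I = 44, II = 16, III = 12,
                                                    IV = 8),
                                 class4_week = 10) {
  stopifnot(subset_size <= n_roots, sum(destiny_counts) == n_roots)
  set.seed(seed)
  destinies <- rep(names(destiny_counts), times = destiny_counts)
  # angularly ordered emergence (quasi-2D volume: roots fan out in-plane)
  fan <- seq(-50, 50, length.out = n_roots)[sample(n_roots)] +
    stats::rnorm(n_roots, 0, 3)
  trajectories <- lapply(seq_len(n_roots), function(i) {
    destiny <- destinies[i]
    dr <- type_diameter_range(destiny)
    lr <- type_length_range(destiny)
    traj <- list(
      destiny = destiny,
      emergence = switch(destiny,
                         I = sample(2:8, 1), II = sample(2:4, 1),
                         III = sample(2:3, 1), IV = 2),
      thicken_week = switch(destiny, I = NA, II = sample(3:5, 1),
                            III = sample(4:6, 1), IV = 5),
      class4_week = class4_week,
      d_cross = stats::runif(1, 0.5, 1.5),
      d_target = stats::runif(1, dr[1], dr[2]),
      length_max = stats::runif(1, lr[1], lr[2]),
      grow_weeks = stats::runif(1, 4, 8),
      emergence_deg = fan[i]
    )
    traj$axis <- make_axis(traj$length_max, traj$emergence_deg)
    traj
  })
  # fixed canvas from the fully grown system so all weeks share one geometry
  full <- lapply(trajectories, function(tr) {
    d13 <- diameter_at_week(tr, 13)
    rpx <- d13 / 2 / mm_per_px
    c(min(tr$axis[, 1]) / mm_per_px - rpx, max(tr$axis[, 1]) / mm_per_px + rpx,
      min(tr$axis[, 2]) / mm_per_px - rpx, max(tr$axis[, 2]) / mm_per_px + rpx)
  })
  m <- do.call(rbind, full)
  margin <- 12
  W <- ceiling(max(m[, 2]) - min(m[, 1])) + 2 * margin
  H <- ceiling(max(m[, 4]) - min(m[, 3])) + 2 * margin
  canvas <- c(H, W, margin - floor(min(m[, 1])), margin - floor(min(m[, 3])))

  scenes <- expand.grid(subset = seq_len(n_subsets), week = weeks)
  scenes <- scenes[, c("week", "subset")]
  subsets <- vector("list", nrow(scenes))
  truths <- vector("list", nrow(scenes))
  for (si in seq_len(nrow(scenes))) {
    wk <- scenes$week[si]
    present <- which(vapply(trajectories, function(tr) tr$emergence <= wk,
                            logical(1)))
    cur_type <- vapply(trajectories[present], function(tr) {
      as.character(c("I", "II", "III", "IV")[
        width_class(diameter_at_week(tr, wk))])
    }, character(1))
    sel <- stratified_pick(present, cur_type, subset_size)
    subsets[[si]] <- sel
    roots <- lapply(sel, function(i) root_at_week(trajectories[[i]], wk,
                                                  mm_per_px))
    truths[[si]] <- root_truth(roots)
  }
  structure(
    list(trajectories = trajectories, scenes = scenes, subsets = subsets,
         truths = truths, canvas = canvas, mm_per_px = mm_per_px,
         weeks = weeks, seed = seed),
    class = "root_series"
  )
}

#' @export
print.root_series <- function(x, ...) {
  cat(sprintf(
    "<root_series> %d roots, weeks %d-%d, %d scenes (%d x %d px canvas)\n",
    length(x$trajectories), min(x$weeks), max(x$weeks), nrow(x$scenes),
    x$canvas[1], x$canvas[2]))
  invisible(x)
}

# proportional (largest remainder) stratified sampling without replacement
stratified_pick <- function(ids, strata, k) {
  tab <- table(strata)
  quota <- floor(k * tab / sum(tab))
  rem <- k - sum(quota)
  if (rem > 0) {
    frac <- k * tab / sum(tab) - quota
    add <- names(sort(frac, decreasing = TRUE))[seq_len(rem)]
    quota[add] <- quota[add] + 1
  }
  sel <- integer(0)
  for (st in names(quota)) {
    pool <- ids[strata == st]
    q <- min(quota[[st]], length(pool))
    sel <- c(sel, if (length(pool) == 1L) pool else sample(pool, q))
  }
  sort(sel)
}

# root_spec of a trajectory at a given week (truncated axis, current profile)
root_at_week <- function(traj, week, mm_per_px) {
  L <- length_at_week(traj, week)
  d <- diameter_at_week(traj, week)
  stopifnot(L > 0)
  seg <- sqrt(diff(traj$axis[, 1])^2 + diff(traj$axis[, 2])^2)
  cs <- c(0, cumsum(seg))
  n_keep <- findInterval(L, cs)
  ax <- traj$axis[seq_len(min(n_keep + 1L, nrow(traj$axis))), , drop = FALSE]
  if (nrow(ax) >= 2) {
    # trim the last vertex to the exact arc length
    excess <- cs[min(n_keep + 1L, length(cs))] - L
    if (excess > 0) {
      v <- ax[nrow(ax), ] - ax[nrow(ax) - 1, ]
      vl <- sqrt(sum(v^2))
      ax[nrow(ax), ] <- ax[nrow(ax), ] - v / vl * min(excess, vl * 0.99)
    }
  }
  cls <- width_class(d)
  type <- c("I", "II", "III", "IV")[cls]
  root_spec(type, ax, make_profile(L, d, d_tip = min(0.4, d)), d)
}

#' Render one scene of a time series
#'
#' @param series a [generate_time_series()] result.
#' @param scene_id row index into `series$scenes`.
#' @param shading render shading.
#' @return A `root_scene` with the scene's frame and truth.
#' @export
render_series_scene <- function(series, scene_id, shading = TRUE) {
  stopifnot(scene_id >= 1, scene_id <= nrow(series$scenes))
  wk <- series$scenes$week[scene_id]
  sel <- series$subsets[[scene_id]]
  roots <- lapply(sel, function(i)
    root_at_week(series$trajectories[[i]], wk, series$mm_per_px))
  # scene-specific but deterministic colour jitter and paint order (the
  # front/behind order of crossing roots is random in a real crown)
  set.seed(series$seed * 1000L + scene_id)
  roots <- roots[sample(length(roots))]
  fr <- render_root_scene(roots, series$mm_per_px, canvas = series$canvas,
                          shading = shading)
  structure(
    list(frame = fr, truth = series$truths[[scene_id]], roots = roots,
         mm_per_px = series$mm_per_px, seed = series$seed,
         week = wk, subset = series$scenes$subset[scene_id]),
    class = "root_scene"
  )
}

#' Write a synthetic dataset to disk
#'
#' Images as PNG, per-scene truths as JSON, plus a long-format CSV
#' (scene, bin, length_mm) and a manifest recording the seed and parameters.
#'
#' @param scenes list of `root_scene` objects.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_scene_dataset <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    png::writePNG(sc$frame$pixels / 255,
                  file.path(dir, sprintf("scene_%03d.png", i)))
    jsonlite::write_json(
      list(scene = i, mm_per_px = sc$mm_per_px, seed = sc$seed,
           fine = as.list(sc$truth$fine), class_mm = sc$truth$class_mm),
      file.path(dir, sprintf("scene_%03d.json", i)), auto_unbox = TRUE,
      digits = NA)
    long[[i]] <- data.frame(scene = i, bin = names(sc$truth$fine),
                            length_mm = as.numeric(sc$truth$fine))
  }
  utils::write.csv(do.call(rbind, long), file.path(dir, "truth_long.csv"),
                   row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_scenes = length(scenes),
         seeds = vapply(scenes, function(s) s$seed, numeric(1)),
         mm_per_px = vapply(scenes, function(s) s$mm_per_px, numeric(1))),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
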