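---
title: "Measuring root diameter distributions with iterative multi-scale ridge detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring root diameter distributions with iterative multi-scale ridge detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Storage-root crops such as cassava form their yield by secondary thickening:
fibrous roots (type I, diameter < 2 mm) transition through intermediate
stages (type II, 2–6 mm; type III, 6–20 mm) into storage roots (type IV,
> 20 mm). Phenotyping this process means excavating root crowns, imaging
them — typically rotating in front of a blue screen — and quantifying, for
each *diameter class*, the total centerline length whose local diameter
falls into that class (the *constituent length*). Excavated crowns combine
millimetre-thin fibrous roots with storage roots several centimetres wide,
often touching or overlapping, which is what makes automated width
measurement hard.

`rootridge` implements a full pipeline for this measurement:

1. **Segmentation.** The blue background is removed with a blueness index
   `beta = 3B - 2.4G - R`, normalized per frame to `beta' = 255 beta /
   max(beta)`; pixels below a threshold `T_beta` are foreground `F`.
   Optional masks remove the stem (`S`, from an external segmentation),
   fixed label regions (`L`), and motion-blurred roots (`C`, the complement
   of dilated Canny edges — blurred roots have no sharp edges). The masks
   combine as `M = F & S & L & C`, refined by a disc erosion of width
   `theta` and removal of fragments smaller than `T_F` pixels to the root
   system mask `RS`.
2. **Ridge detection.** On the background-masked gray image, root
   centerlines are curvilinear bright structures. Following the classic
   Gaussian-derivative scheme, the image is convolved with first- and
   second-derivative Gaussian kernels at scale `sigma`; a pixel is a
   centerline candidate when the second directional derivative along the
   Hessian's principal direction is strongly negative and the first
   directional derivative has a sub-pixel zero inside the pixel. Candidates
   with response above `u` seed lines, candidates above `l = ratio * u`
   extend them (hysteresis linking). The saliency threshold derives from
   the expected center response of a bar of half-width `w` and contrast
   `h`:
   `u = 2 w h / (sqrt(2 pi) sigma^3) exp(-w^2 / (2 sigma^2))`.
3. **Width measurement.** The local diameter at each centerline point is
   the distance between the first admissible local maxima of the absolute
   gradient on both sides of the line normal.
4. **Iteration over scales.** The scale rule `sigma >= w/3` ties the
   smoothing to the largest expected half-width; a single scale that suits
   storage roots erases fibrous roots. The pipeline therefore iterates a
   ladder of `(w, sigma, h)` settings from small to large (`forward`) or
   large to small (`reverse`), protecting previously found centerlines with
   a growing deletion mask so later passes extend rather than overwrite
   earlier ones.
5. **Postprocessing and classification.** Centerlines are dilated by one
   pixel (closing single-pixel gaps), thinned to unit width, masked by
   `RS`, and weighted by a per-tile orientation factor `tau = 1/cos(omega)`
   (`omega` folded into `[0, 45°]`), because a pixel step along a diagonal
   represents `sqrt(2)` times the metric length of an axis-aligned step —
   plain pixel counting under-measures diagonals by up to ~29%. Each
   centerline pixel then contributes `tau * mm_per_px` of length to the
   diameter class containing its local width.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `w` | target half-width of a pass (px) | ladder, geometric | per pass |
| `sigma` | Gaussian scale (px) | `max(w/3, 1)` | `w/sqrt(3)` is the conservative single-scale choice |
| `h` | expected root/background contrast (gray levels) | 25–60 | set below the true contrast; the threshold `u` scales linearly with it |
| `lower_ratio` | hysteresis ratio `l/u` | 0.35 | the commonly quoted range is 0.25–0.5 |
| `gamma_factor` | deletion-tube scale | 0.9 | tube diameter `0.9 *` measured width |
| `tau_min_px` | reverse mode: per-pass minimum diameter | next pass's `w` | |
| `min_width_px` | global minimum accepted diameter | 0 (3 in the validation experiments) | sub-3-px measurements are not meaningful |
| `T_beta` | blueness threshold | 128 | |
| `theta`, `T_F` | erosion width, fragment floor | 0, 0 | clean synthetic scenes need neither |
| `mm_per_px` | metric scale at the rotation axis | user input | the 0.5 mm/px fixture default is arbitrary |

Three to four iteration steps suffice for the diameter ranges of
storage-root crops. The forward direction is the default; reverse is useful
when large roots dominate and requires the per-pass minimum diameter so
that early (large-scale) passes do not absorb thin roots.

## Numerical design choices

Several choices in this implementation deserve a note, because the
underlying method leaves them open:

* **Sub-pixel acceptance at 0.6 px.** On flat-topped profiles whose true
  center falls on a pixel boundary, the Taylor estimate of the
  first-derivative zero overshoots slightly; a strict 0.5-px test loses
  both center-adjacent pixels. The acceptance bound is therefore 0.6 px,
  and the seed test applies a 0.9 sampling-slack factor to `u` because the
  pixel grid samples the response peak of an even-width structure a few
  percent below its analytic maximum.
* **Edge search length.** With `sigma = w/3`, a search of `2.5 sigma`
  (= `0.83 w`) cannot reach the edges of a maximal root; the search runs to
  `w + 2 sigma`.
* **Edge admissibility.** The first local gradient maximum along the
  normal must carry at least half the strongest gradient on its side and a
  fifth of the strongest gradient on either side, the line point itself
  must sit at a gradient minimum (at most half the edge strength), be
  roughly midway between its edges, and be at least as bright as the edge
  positions. These tests reject the spurious responses that rounded,
  front-lit root profiles otherwise produce: shading-slope maxima well
  inside wide roots, responses hugging one silhouette, and tangential
  responses around rounded root ends (the latter are additionally rejected
  by requiring the along-line Hessian eigenvalue to stay below half the
  cross-line magnitude). Points whose edges are corrupted — typically where
  another root crosses — are not dropped but get widths interpolated from
  intact neighbours on the same line, and are flagged; a line with no
  intact point at all is discarded.
* **Band tiling in forward mode.** Every pass except the last only accepts
  measured diameters up to `1.9 w`; passes after the first reject
  diameters below `1.85` times the previous pass's `w`. Without the upper
  cap, hysteresis linking creeps along a tapering root into sections wider
  than the pass can measure (the widths clip at the search range); without
  the lower bound, later passes re-detect already-claimed thin roots a few
  pixels off-center after heavy smoothing. This is the forward-direction
  analogue of the reverse-mode minimum-diameter parameter.
* **Deletion tube.** Each accepted centerline pixel protects a disc of
  diameter `0.9 *` its *measured* width — never wider than the root it
  belongs to, so a protected thin root does not shadow a genuinely thick
  neighbour. Tubes accumulate across passes, so the deletion mask is
  monotone.
* **Consistency with the mask.** A centerline pixel claiming width `W`
  must lie at least `0.3 W` inside the root-system mask; silhouette
  staircase artifacts fail this.
* **Thinning.** Guo–Hall thinning is used because it yields minimal
  8-connected diagonals; the classic two-subiteration scheme leaves
  staircase corner doublets that inflate pixel counts (and hence lengths)
  by several percent.
* **Orientation estimation.** Tile-wise (32 px) histograms over 9
  orientation bins of local skeleton directions (PCA over a 7×7
  neighbourhood); the dominant bin is refined by the circular mean of its
  members, so an exact 45° line gets `tau = sqrt(2)` rather than a bin
  center.

## The synthetic validation data

Validation needs images whose per-class constituent lengths are known
exactly. The generator builds 2D root systems as tapered tubes around
spline-smoothed planar axes (random heading walks with a weak gravitropic
pull), rendered with anti-aliasing and a front-lit Lambertian shading that
gives roots a rounded appearance, on a blue background. The ground truth is
computed *analytically* from each root's piecewise-linear diameter profile
— arc length per fine diameter bin (0–1, 1–2, …, 9–10, 10–15, 15–20,
20–25, 25–30, 30+ mm), merged losslessly into classes 1–4 — and never from
pixels, so it is exact and independent of the rendering resolution.

Scene composition emulates excavated cassava crowns grown in a wide, thin
(quasi-2D) volume: roots share a basal anchor and fan out in angular order
(a 6-mm-deep growth volume leaves no room to cross in depth), with type-
specific maximum diameters (I: 1–1.8, II: 2.8–5.5, III: 7–18, IV: 22–45 mm,
global cap 45 mm) and lengths (I: 6–14, II: 20–40, III: 25–45, IV: 25–50
cm). Storage-type profiles have a proximal neck and mid-root swell, the
typical storage-root shape. The weekly growth model keeps 80 roots with
fixed destinies (44 stay fibrous, 16 transition, 12 early-storage, 8
storage); thickening starts in weeks 3–6 depending on destiny, and
storage-root diameters cross the 20-mm class-4 boundary at week 10 by
construction. Weekly scenes are stratified 17-root subsets whose type
proportions match the full system within one root per type.

What the generator does **not** emulate: real surface texture and dirt,
motion blur, perspective shortening, stems, and 3D crossing order beyond a
random paint order. Passing validation on these scenes therefore
demonstrates the geometry and scale-handling of the method, not robustness
to photographic noise.

## Validation experiments and what they show

Three experiment drivers reproduce the simulation studies (the problem
sizes below are the package defaults used by `scripts/acceptance.R`; the
test suite runs smaller versions of the same drivers):

* `experiment_single_roots()` — 50 single roots per type I–IV at per-type
  resolutions (0.15–0.6 mm/px) that keep the thinnest rendered diameter at
  3 px. Pooled predicted vs. true class lengths (classes 1–4) give R²
  around 0.99 with nRMSE below 0.1: on isolated roots the method measures
  essentially exactly.
* `experiment_one_type()` — systems of one root type (II: 16, III: 12,
  IV: 8 roots — cassava bears roughly 3–10 storage roots) at the video-box
  resolution of 0.6 mm/px, classes 2–4 pooled.
* `experiment_time_series()` — weeks 2–13, five 17-root subsets per week,
  classes 2–4 pooled over all weeks.

In the two system-level experiments a single 2D view of a clustered crown
is analysed, and part of the true constituent length is simply invisible:
roots lie behind one another, and partially covered roots are measured at
their visible sliver width. Accounting on representative scenes attributes
roughly 15–25% of thick-class truth to occlusion or crossings, which caps
single-view recovery; rotating-view aggregation (`aggregate_frames()`),
which the pipeline supports for real image sequences, exists precisely to
remove this effect. System-level agreement therefore depends as much on
the occlusion statistics of the scenes as on the measurement core, and
crowns drawn by a different architecture model will score differently. The
package reports what it measures, and the validation harness
(`regression_stats()`, `compare_class_lengths()`, `mask_metrics()`) makes
the comparison explicit.

The per-scene problem sizes (images of roughly 0.3–1.2 megapixels, 200
single-root scenes, 15 systems, 60 weekly scenes) were chosen so that the
full validation completes in minutes on a single CPU.

## Worked example

```{r, eval = FALSE}
library(rootridge)

scene <- generate_root_system(6, "III", mm_per_px = 0.6, seed = 31)
m <- measure_scene(scene, h = 40)
summary(m)
plot(m)           # centerlines coloured by diameter class
compare_class_lengths(m$distribution, scene$truth)
```

For real images, load frames from a directory, segment with your own
thresholds, and run a plan sized to the largest expected root:

```{r, eval = FALSE}
frames <- load_frames("path/to/frames")     # TIF/PNG sequence
cal <- camera_calibration(mm_per_px = 0.6)  # measure this for your setup!
plan <- iteration_plan(w_max = 40, h = 40)  # half-width in px
res <- analyze_frames(frames, plan, cal = cal,
                      seg = segmentation_params(T_beta = 128, theta_px = 1,
                                                T_F = 50))
res$aggregate
```

## Known limitations

* A single 2D view cannot see occluded root sections; use rotating
  sequences and `aggregate_frames()` where possible.
* Diameters at or below ~3 px are not measurable; choose the imaging
  distance so the smallest class of interest stays above that.
* Widths of strongly shaded wide roots carry a small inward bias (the
  gradient maximum of a rounded, front-lit profile sits slightly inside
  the silhouette); no profile-asymmetry bias correction is applied.
* Touching parallel roots of similar brightness can merge into one
  detection; crossing roots locally corrupt widths (interpolated from
  neighbours).
* Root topology (connecting segments into whole roots) and root counting
  are out of scope: the output is a per-pixel width map and its class
  statistics.
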