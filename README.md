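# rootridge

Quantifies the **root-diameter distribution** of excavated storage-root
crops (cassava and similar species) from images of root crowns in front of
a blue background — single photographs or frame sequences from a rotating
video box.

Breeders and root physiologists track storage-root formation through the
*constituent length* per diameter class: the total centerline length whose
local diameter falls below 2 mm (fibrous), between 2–6 mm (transition),
6–20 mm (early storage), or above 20 mm (storage roots). Measuring this
automatically is hard because one crown mixes millimetre-thin and
centimetre-thick roots, often touching and overlapping.

## The method

The pipeline has two stages:

1. **Segmentation.** Background removal with a normalized blueness index
   (β = 3B − 2.4G − R; pixels with β′ = 255·β/max β below a threshold
   T<sub>β</sub> are foreground), combined with stem, label and motion-blur
   masks via `M = F ∧ S ∧ L ∧ C`, then erosion and fragment filtering into
   the root-system mask RS.
2. **Iterative multi-scale ridge detection.** Root centerlines are
   curvilinear bright structures in the masked gray image. A
   Gaussian-derivative ridge detector locates sub-pixel centerline points
   (zero first directional derivative, strong second derivative across the
   line) with hysteresis thresholds derived from

   u = 2wh / (√(2π) σ³) · exp(−w² / 2σ²),

   the expected center response of a root of half-width *w* and contrast
   *h* at scale σ (with σ ≥ w/3), and measures a width at every centerline
   point from the gradient maxima perpendicular to the line. Because no
   single scale covers both fibrous and storage roots, the detector
   iterates a ladder of (w, σ, h) settings; a growing deletion mask
   protects earlier centerlines from being overwritten. Centerlines are
   then thinned, masked, and weighted by a per-tile orientation factor
   τ = 1/cos ω (up to √2 for diagonals — plain pixel counting
   under-measures a 45° segment by ≈29%). Every centerline pixel finally
   contributes τ·mm_per_px of length to the class of its local diameter.

The package also ships a **synthetic root-scene generator** with exact
analytic ground truth (single roots, one-type systems, a 12-week growth
series) and a **validation harness** (identity-line R², nRMSE normalized by
the truth's standard deviation, mask IoU, a perspective-shortening model),
so the whole accuracy study can be reproduced from code.

## Worked example

```r
library(rootridge)

scene <- generate_root_system(6, "III", mm_per_px = 0.6, seed = 31)
m <- measure_scene(scene, h = 40)
m
```

```
Root width analysis
  centerline pixels: 2535
<diameter_distribution>
  class 1 (<2 mm):     87.2 mm    5.1%
  class 2 (2-6 mm):    470.6 mm   27.4%
  class 3 (6-20 mm):   1157.5 mm   67.4%
  class 4 (>20 mm):      1.4 mm    0.1%
  total   1716.7 mm over 2535 centerline px
```

The scene is a crown of six early-storage roots; the analysis finds 1.72 m
of centerline, two thirds of it at early-storage diameters. Against the
generator's analytic truth:

```r
compare_class_lengths(m$distribution, scene$truth)
```

```
  class     pred_mm  truth_mm    error_mm  error_pct phantom
1     1   87.245146  158.1945  -70.949343 -44.849440   FALSE
2     2  470.564624  490.0012  -19.436567  -3.966637   FALSE
3     3 1157.542165 1427.3644 -269.822217 -18.903527   FALSE
4     4    1.390913    0.0000    1.390913         NA    TRUE
```

Class 2 agrees within 4%; class 3 is ~19% short because a single 2D view
cannot see roots hidden behind others (class 1 is below the resolution
limit at 0.6 mm/px, and the 1.4 mm of "class 4" is a phantom where two
touching roots merge). `plot(m)` overlays the centerlines on the image,
coloured by class. For rotating-box sequences, `load_frames()` +
`analyze_frames()` average the distributions over all perspectives, which
is the standard way to recover occluded material.

## Command line

A thin CLI over the package functions lives at `inst/cli/rootridge.R`:

```sh
Rscript inst/cli/rootridge.R analyze  --input frames/ --out results/ --w-max 40
Rscript inst/cli/rootridge.R simulate --out dataset/ --kind system --type III --n 5
Rscript inst/cli/rootridge.R validate --dataset dataset/ --pred pred.csv --out report.json
```
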