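---
title: "Methods: machine-vision phenotyping of mushroom caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: machine-vision phenotyping of mushroom caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cappheno)
```

## The problem

Breeding programs for shiitake mushrooms select strains by cap traits — size,
shape, color, and above all weight. Manual measurement with calipers and
scales is slow and error-prone, so the pipeline implemented here measures a
cap from a single top-down photograph taken on a uniform colored background:
it separates the cap from the background, locates its edge, computes eleven
morphometric and color traits, and predicts cap weight from the traits most
correlated with it. Because imaging rigs differ and no reference image set
ships with the package, a seeded synthetic-cap generator provides scenes
with exact ground truth for every stage.

## Pipeline stages and their assumptions

### Segmentation (KD-seeded k-means)

Pixels are clustered in RGB space with `k = 2` (cap vs background). Seeding
matters for Lloyd's algorithm, so initial centers are taken from the leaves
of a KD-tree built over the pixel colors (leaf size 32, leaf mean as
representative) and chosen to greedily maximize their minimum pairwise
separation. On instances with few candidate seeds (at most 56 seed subsets)
the fit runs Lloyd from every subset and keeps the lowest inertia, which on
small instances reaches the exhaustive-partition optimum the tests check
against. The background cluster is identified by majority vote over the
frame-border pixels — valid because the protocol photographs one cap
centered on a uniform background; the vote ties only in pathological
half-and-half frames, which is reported as an error rather than guessed.
Post-processing keeps the largest 8-connected component and fills interior
holes so that surface cracks never puncture the cap region.

### Edge chain

The classical chain follows fixed steps: BT.601 grayscale, Gaussian blur
(sigma 1.4, kernel 5, reflective borders), Sobel gradient magnitude, texture
suppression, Otsu thresholding (strict `>`, 256-bin histogram), Moore
contour tracing, and elimination of contours enclosing less than
`min_area` (50 px^2 at 512 x 512, scaled with image area). The returned
edge map contains the traced outer contours of the surviving components, so
predictions stay about one pixel thick no matter how wide the thresholded
gradient band is; the surviving-contour count refers to outer contours,
since a thresholded boundary band is a ring whose interior hole would
otherwise always add an inner contour.

A featureless frame (constant gradient) yields an empty edge map and count
zero rather than an Otsu error.

### Texture suppression

Dry caps develop radial surface cracks whose gradient response rivals the
cap edge. The suppression stage scores local texture and damps the gradient
where texture is high:

* `lbp8` computes 8-neighbor local binary patterns (radius 1, clockwise from
  the top-left, bit set when neighbor >= center, border code 0).
* `texture_score` is the windowed fraction (default 9 x 9) of *non-uniform*
  codes — more than two circular 0/1 transitions. Smooth step edges produce
  uniform codes; pixel-scale roughness produces non-uniform ones.
* `semi_gaussian_suppress` multiplies the gradient by a weight that is 1
  up to a score threshold `tau = 0.25` and rolls off as
  `exp(-(s - tau)^2 / (2 sigma_s^2))`, `sigma_s = 0.25` — identity below
  threshold, smooth half-Gaussian decay above it, never amplifying.

Two practical facts shape how the chain feeds this score. First, the
comparison in `lbp8` is scale-free, so any sensor noise — however small —
randomizes the codes of flat regions. The chain therefore computes the LBP
on a coarsely quantized copy of the *unblurred* grayscale (step 32):
noise-level differences collapse to exact equality while genuine surface
texture spans several bins. (Blurring before the LBP would be
counterproductive: it removes exactly the pixel-scale structure the
descriptor needs.) Second, the non-uniform fraction saturates near 0.445
even on a completely random field — with the >= convention, locally extreme
pixels always produce the uniform codes 0 or 255 — so the chain normalizes
the score by that plateau and clips to [0, 1], making "fully textured" map
to 1. With the plateau normalization the pinned `tau`/`sigma_s` defaults
suppress crack fields by an order of magnitude while leaving the smooth cap
boundary untouched. A related consequence, worth stating because it is easy
to get wrong: a one-pixel checkerboard scores 1/2, not 1 — half of its
pixels (the low phase) are local minima and carry the uniform code 255
under any fixed comparison convention.

### Trait measurement

Eleven traits per cap, from the mask and its outer contour:

| Trait | Method | Notes |
|---|---|---|
| External rectangular length/width | minimum-area rotated rectangle (rotating calipers on the convex hull) | length >= width by swap |
| Roundness | width / length | bounded in (0, 1]; see below |
| Area | shoelace on the outer contour polygon | |
| Perimeter | subsampled contour polygon (stride 3) | see below |
| Long/short axis | moment-equivalent ellipse (4 sqrt of covariance eigenvalues) | closed-form testable |
| Red/Green/Blue/Greyscale mean | arithmetic means over the mask | greyscale from the rounded BT.601 image |

Roundness is implemented as width/length even though the trait is named a
"ratio of length to width": in the published summary statistics the mean
roundness is 0.81 with near-equal mean length and width, which only the
bounded width/length reading reproduces.

Perimeter needs care on rasters: the Euclidean chain length of a traced
boundary overestimates a smooth curve by about 5% (staircase effect), so the
trait uses the classic subsampled-polygon estimator (every 3rd vertex),
whose bias is under 1% across the cap geometries tested; the plain Euclidean
sum remains available and is the default of `contour_perimeter`. Shoelace
area on pixel-center polygons is biased low by roughly `2 * 0.5 / r`
(about 2% at r = 50 px, worse for small caps), which the tests acknowledge
by using fixtures of at least 50 px radius.

Calibration multiplies lengths by `mm_per_px` (default 0.043, a fixed
working-distance rig constant verified against 5, 3 and 1 mm ruler scales)
and area by its square; color means and roundness are dimensionless. Traits
are computed in pixels first and both scales can be reported, because
published summary tables of this kind are often ambiguous about their units
(the bundled example table prints areas near 208 alongside lengths near 60,
consistent with neither px^2 nor mm^2).

### Edge evaluation

`match_edge_maps` pairs predicted and true edge pixels one-to-one within a
tolerance of 0.0075 x image diagonal (the convention of the standard
contour benchmarks; the source study states none). Matching starts greedy
nearest-first with deterministic tie-breaks and is completed by augmenting
paths to maximum cardinality, so the true-positive count equals the optimal
bipartite assignment and is symmetric between prediction and truth.
Precision, recall and F use the zero-denominator-gives-zero convention.

Dataset summaries follow the standard definitions: ODS is the best pooled-F
over a fixed threshold sweep; OIS pools the counts taken at each image's own
best threshold; AP is the trapezoidal area under the recall-sorted,
monotone-interpolated precision curve. One naming caveat: some reports gloss
OIS as the *mean* of per-image best F. Under that reading OIS >= ODS is not
a theorem (a pooled F can exceed a mean of per-image Fs by rounding-level
amounts), whereas with count pooling binary predictions give OIS = ODS
exactly and probability maps gain from per-image adaptation; this package
uses count pooling and also returns the per-image best-F vector.

### Weight model

Features and weight are min-max normalized to [0, 1] (the normalization the
study's comparison plots imply; it names no scheme). An RBF
epsilon-SVR maps a feature group to weight; its hyperparameters
`(C, gamma, epsilon)` are tuned by a canonical Grey Wolf Optimizer — 20
wolves, 100 iterations by default, positions clipped to log10-space bounds
C in [1e-2, 1e3], gamma in [1e-4, 10], epsilon in [1e-3, 1] — minimizing
the mean 5-fold cross-validated RMSE. An epsilon tube wider than the
response spread leaves the SVR with no support vectors; such configurations
are scored as training-mean predictors instead of erroring, so the
optimizer can traverse them. Error metrics are reported in normalized units
and grams, since published RMSE values of this kind (0.038 on 50-200 g
caps) are only plausible on the normalized scale.

The four canonical input groups are nested: M1 {Area, Perimeter, External
rectangular width, Long axis} down to M4 {Perimeter}. They are fixed (the
published grouping), with a data-driven mode that instead nests the top of
the computed correlation ranking. Features with |r| < 0.01 are excluded
from the ranking. Note two quirks inherited from the source material and
kept deliberately: the prose and the table disagree about whether M1 is the
largest or smallest group (the table's reading, M1 largest, is the
self-consistent one and is used), and the greyscale mean ranks third by
correlation yet is absent from every fixed group.

The LSTM-family comparison models (LSTM, BiLSTM, attention and
Bayesian-tuned variants) are intentionally not implemented: no architecture
or sequence construction for tabular input is specified anywhere, and the
source's own comparison finds them inferior to the SVR at this sample size.
`fit_gwo_svm`'s factory signature is the plug-in point for adding them.

## The synthetic generator

`gen_cap_image` renders one elliptical cap (rotated, default 512 x 512
frame) on a red or green background, with exact ground truth: the filled
mask, the one-pixel Moore-traced boundary curve, and analytic phenotype
values (area pi*a*b, Ramanujan perimeter, axes 2a and 2b, oriented box,
color means over the painted pixels). Default background colors are
(190, 40, 40) red and (50, 160, 70) green, and the default cap color
(110, 60, 35) is a brown whose luminance (72) contrasts with the green
background (117) but barely with the red (85) — deliberately mirroring the
reported behavior of intensity-based detectors, which degrade on red.
Surface cracks are jagged radial polylines, strictly interior so the true
edge stays unambiguous, rendered as a fissure whose floor has per-pixel
random depth (up to `crack_contrast`) and whose margin carries pixel-scale
brightness roughness with no net depression: the pixel-scale roughness is
the feature that distinguishes crack texture from the smooth cap boundary
for the LBP stage, as it does on real weathered caps. Noise is i.i.d.
Gaussian per channel, clipped to [0, 255]. All randomness derives from the
spec's seed and the caller's RNG state is restored.

`gen_weight_table` draws the eleven features independently and uniformly
over per-trait ranges chosen to match the published summary table, and sets
`weight = intercept + sum(beta_f * z_f) + noise` on range-normalized
features. With independent features the population correlations are
`beta_f * sigma_z / sd(weight)`, which caps their sum of squares at 1 — the
published per-feature correlations (0.91, 0.9, 0.74, ...) are jointly
unreachable without inter-feature correlation, so the defaults reproduce
the published *ranking*, not the magnitudes, with adjacent effect sizes
separated enough to be resolvable at a few hundred rows. The default
intercept centers mean weight at 125 g so caps fall inside the 50-200 g
calibration window.

What the generator does not emulate: lighting gradients, specular
reflections, water stains, camera distortion, multi-cap scenes, or
photorealistic cap texture. Passing the synthetic suite therefore shows the
pipeline's logic is correct under its stated assumptions, not that it is
robust to every artifact of a real rig.

## Verification strategy and problem sizes

Every optimized path is tested against an independent brute-force oracle:
dense index-by-index convolution for the Gaussian and Sobel kernels (1e-9),
per-pixel bit assembly for the LBP, exhaustive 2-partition enumeration for
k-means on up to 8 points, maximum bipartite matching for the edge matcher,
and closed forms for contour measurements. Property suites cover
suppression monotonicity, metric identities (rmse^2 = mse, harmonic-mean F,
fold-partition exactness, monotone optimizer traces), and scale/rotation
equivariance of the traits.

The end-to-end suites run at deliberate desk scale: 20 seeded 512 x 512
scenes (green background, up to 12 cracks, noise up to 8) for edge quality
— the chain reaches ODS about 0.99 there — and five replicate n = 500
tables for weight-model recovery (10 wolves, 20 iterations for the tuner in
these runs), where the cross-validated R^2 is about 0.98 and the normalized
RMSE about 0.03. `scripts/acceptance.R` recomputes all of these from
scratch under a caller-supplied seed.

## Known limitations

* The classical grayscale chain needs luminance contrast between cap and
  background; on the red background it degrades sharply (the color-space
  segmentation does not). Green is the reference background throughout.
* The deep six-block edge path is a reduced-width forward pass only
  (cluster mask concatenated to blocks 1-2, suppression weight on block-2
  features, averaged sigmoid side outputs); no trained weights ship and no
  training loop is provided.
* Shoelace area under-measures small caps (about 3% at 30 px radius);
  calibrated areas inherit this.
* The weight model interpolates; predictions far outside the training trait
  ranges trigger a warning but are still extrapolations.
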