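---
title: "Methods: seed grading from shape, color and texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed grading from shape, color and texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedvision)
```

This vignette is the package's own account of its method: the model and
its assumptions, the parameters that matter, the numerical choices made
where the underlying procedure left them open, and what the synthetic
benchmark does and does not demonstrate.

## The grading model

A seed is graded by surface appearance along two independent aspects:

* **form** — good seeds are plump and near-elliptical; triangular,
  elongated or irregular outlines indicate broken, immature or off-type
  seeds;
* **surface** — a dark reddish-brown or black coat indicates sound
  condition; a gray or whitish coat indicates staleness, and dark spots
  or heavy roughness indicate damage.

Each aspect gets its own three-layer sigmoid back-propagation network
(shape features for the first; color and texture features for the
second), and the final grade is the conjunction: a seed passes only when
both networks output *good*. The AND rule encodes the asymmetry of the
sorting task — a seed that fails either aspect is a reject, so the
combined classifier can only be more conservative than either network
alone. Both networks are trained on the same global good/NG label, which
makes each one's training set noisy in the region where only the *other*
aspect is defective; the AND combination is what recovers the joint rule.

## Segmentation

Frames show bright seeds on a dark field. The gray image (R+G+B)/3 is
thresholded — Otsu's method by default, a fixed threshold for
reproducibility studies — then hole-filled, opened with a disc of radius
2 px (one erosion, one dilation), and hole-filled again. Filling **before**
the opening is deliberate: dark surface defects can fall below the
threshold, and eroding a hole-riddled mask can split one seed into
fragments. Foreground components are labeled with 8-connectivity
(background: 4-connectivity, the standard dual pair), components under
`min_area` = 50 px are discarded as dust, and each region's boundary is
traced by Moore neighbor following.

Assumptions: seeds do not touch (touching seeds merge into one region by
construction of connectivity), and the background is darker than every
seed class. Both hold for the capture geometry emulated here (one seed
per vacuum hole on a dark disk).

## Shape descriptors and sub-pixel conventions

All fifteen form descriptors derive from a geometry summary of the
region. Where the defining formulas speak about the continuous shape, a
few estimator choices matter on a pixel lattice:

* **Perimeter.** Raw chain-code length (diagonal steps √2) overestimates
  smooth boundaries by ~5–6%, which would push circularity 4πA/P² of a
  disk down to ≈0.89. The default estimator anchors on the convex hull
  of the contour points (hull polygon length is staircase-free), adds
  concave detours measured on a smoothed copy of the contour (circular
  moving average, window 5), and applies a quarter-pixel outward offset
  (+π/2). The raw chain length remains available
  (`contour_perimeter(..., method = "chain")`).
* **Quarter-pixel corrections.** Boundary pixel centers sit inside the
  generating contour by between zero (smooth extrema) and ~0.7 px
  (polygon corners) depending on local orientation. Feret diameters are
  therefore corrected by +0.5 px and the minimum-enclosing-circle radius
  by +0.25 px. With these conventions, rasterized primitives (disk
  r = 40, 100×50 rectangle, 5:3 ellipse) reproduce their closed-form
  circularity, elongation, eccentricity and defect ratio within 2%
  (`tests/testthat/test-shape.R`).
* **Moment ellipse.** The semiaxes (a ≥ b) come from the second central
  moments of the pixel set with the standard 1/12 pixel-extent term;
  a = 2√λ₁ reproduces the generating radius exactly for solid disks and
  ellipses. A region whose minor-axis spatial variance vanishes (a
  collinear pixel run) is rejected as degenerate.
* **Quadrant areas.** The symmetry area ratios partition the pixels by
  the two principal axes through the centroid. Axis directions are made
  canonical by the sign of the third moment along each axis, trig values
  within 1e-12 of zero are snapped so that 90° lattice rotations are
  exact congruences, and pixels lying exactly on an axis are shared
  half-half between adjacent quadrants — this makes the ratios exactly
  zero for mirror-symmetric shapes and exactly invariant under 90°
  rotations and flips.
* **Out-of-roundness.** Defined as (R_max − R_min)/R_mean over
  centroid-to-contour radii. Radii are measured on the smoothed contour:
  extreme radii to raw pixel centers carry half-pixel staircase noise
  that the ratio would amplify (the smoothed version is stable within 2%
  under 2× upsampling; the raw one is not).
* **Hull features.** The convex-hull interior angles and the deepest
  convexity defect (maximum perpendicular contour-to-hull distance) have
  no canonical formula in the source material for this pipeline; the
  definitions above are this package's documented choices, selected to
  be rotation invariant and to separate convex from lobed outlines.

## Color descriptors

Means over mask-true pixels only, in the geometric HSI model:
I = (R+G+B)/3, S = 1 − 3·min(R,G,B)/(R+G+B), H by the arccos formula
reflected to 360° − θ when B > G, with H := 0 for achromatic pixels.
The reported gray mean equals the intensity mean by construction (the
historical feature lists name both; the implementation treats I_mean as
an alias of the gray mean). Hue is reported as degrees/360 and averaged
arithmetically by default, matching common practice in this application
area; this misbehaves for hues straddling the 0°/360° wrap (two reds at
1° and 359° average to mid-scale), so a circular mean is available via
`color_features(..., circular_hue = TRUE)`. Seed-coat hues here live in
the red–yellow range, far from the wrap.

## Texture descriptors

The gray-level co-occurrence matrix quantizes gray to 16 equal-width
bins over [0, 255] (default; the bin count trades resolution against
sampling noise in a ~1000-px region), counts ordered pairs at distance 1
in each of the four orientations 0°/45°/90°/135°, restricted to pairs
with both pixels inside the mask, and normalizes to sum 1. Four
statistics are taken per orientation — angular second moment Σp²,
entropy −Σ p ln p (natural log; the conventional negative sign, so
entropy is nonnegative), contrast Σ(i−j)²p, homogeneity Σp/(1+(i−j)²) —
and averaged over the orientation set, which is closed under 90°
rotation. A brute-force pair-enumeration oracle verifies the matrix
exactly on 8×8 images over 1000 seeded trials.

The local-similarity operator assigns each interior pixel the fraction
of its 8 neighbors whose gray difference from the center is at most
`similarity_t` = 10 gray levels; since all 8 neighbors are counted, the
value is invariant to neighborhood rotation. Its mask average is near 1
for smooth coats and drops in the presence of spots or roughness.
Coarseness follows Tamura: per pixel, the dyadic window size 2^k
(k ≤ 4, window 16 px — seeds here are ~30–40 px across) maximizing the
directional difference of window averages, averaged over the mask.
Neither operator has a full specification in the source material for
this pipeline (which cites external references); both definitions are
documented package choices with the stated invariance.

## The networks

Architecture and training follow the classical recipe: logistic sigmoid
units in the hidden and output layers, hidden width nh = ⌈(n_i+n_o)/2⌉
(ceiling — the reference architectures map both 10 and 9 inputs to 6
hidden nodes, which forces rounding up), two output units with one-hot
targets, min-max input normalization to [0, 1] with bounds stored in the
model (validation rows clip), online per-sample gradient descent at
learning rate 0.01 under mean-squared-error loss, per-epoch reshuffling,
and termination when the epoch-mean MSE falls below 0.01 (tolerance) or
at `max_epochs`, in which case the model is flagged non-converged but
still returned — with noisy labels the Bayes MSE exceeds the tolerance,
and the argmax decision is still well defined. Weights initialize
uniformly in [−0.5, 0.5]. Initialization, shuffling and updates are
driven by a dedicated splitmix64 generator seeded from `rng_seed`, so
training is bit-reproducible and independent of R's RNG state. The
per-sample update loop is compiled (Rcpp); the forward pass, loss and
analytic gradient also exist as plain-R reference implementations, and a
central-difference check verifies the gradient to 1e-6 relative error.

Prediction takes the argmax of the two output activations; an exact tie
goes to NG (the conservative direction for a sorting line).

## Feature selection

Sequential floating forward selection starts from a basic feature (the
best single feature: out-of-roundness for the shape pool, mean gray for
the color–texture pool), and alternates greedy forward additions with
conditional backward removals. The criterion is the validation accuracy
of a network trained on the candidate subset — a single train/validation
split, fully seeded, so every subset has one deterministic score and the
whole trace is reproducible. Unstated details fixed here: the forward
step always adds the argmax-gain feature (ties to the lowest feature
number); a removal fires only when it *strictly* beats the best score
previously recorded at the smaller size, and the feature just added is
never removed immediately; the search stops when the pool is exhausted,
at `max_steps` = 30 recorded steps, or when the best available addition
no longer strictly improves on the best score previously seen at the
resulting size. On crafted criterion tables over ≤5 features (including
one where the optimum is reachable only through a floating removal) the
returned subset equals exhaustive search.

## The synthetic generator

`make_frame()` renders anti-aliased star-convex blobs on a dark field
(gray 5) in a 3×7 grid of 21 cells at desk scale (400×400 px; the full
capture-resolution geometry is supported but unnecessary for testing).
Shape classes are radius functions: circle, ellipse (axis ratio
1.35–1.6), elongated ellipse (2.2–3.0), three-lobed "triangular" outline
(cos 3φ, amplitude ≈ 0.22), and random-harmonic irregular outlines.
Surface color classes are reddish-brown (165, 95, 60), brown-black
(118, 106, 96), gray (172, 170, 168) and white (200, 196, 188) — the two
good classes share a dark gray level (~105) and differ in saturation,
while reject classes are pale, mirroring how coat condition presents
under ring lighting. Each seed gets multiplicative radial shading
(edges 25% darker), additive Gaussian roughness (σ 1–4 gray levels), and
Poisson-placed dark spots covering a controllable area fraction.

The ground-truth rule *is the generator's own definition* of the
phenotype: good ⇔ shape ∈ {circular, oval} AND color ∈ {reddish-brown,
black} AND spot density < 0.02. NG seeds sample a defect pattern (shape
only, color only, spots only, or mixed) so that single-aspect defects
dominate — the regime in which the AND rule matters. Feature tables come
from actually rendering each seed and running the real segmentation and
descriptor stack; nothing is sampled from feature-space distributions.

What passing the synthetic benchmark shows: the pipeline's stages
compose correctly, the descriptors separate the generator's phenotypes,
selection and training are stable, and the AND rule recovers a
conjunctive rule from noisy per-aspect labels. What it does not show:
performance on real seed images — real coats have correlated,
non-Gaussian texture, specular highlights, dust, touching seeds and
out-of-plane pose variation that the generator deliberately omits.

## Problem sizes and reproducibility

The acceptance suite trains on 300 seeds (150 good / 150 NG), selects
features against a 200-seed validation split, and evaluates the combined
classifier on 400 held-out seeds — population sizes chosen so the full
render→segment→select→train→test cycle stays comfortable on a laptop
while keeping binomial noise on the reported accuracy near one
percentage point. Subset-criterion fits use a 300-epoch budget and the
final networks 1500 epochs; with noisy per-aspect labels the epoch-MSE
plateaus long before either budget. Every random quantity (rendering,
initialization, shuffling) descends from explicit integer seeds.

## Known limitations

* Arithmetic hue averaging (default) is wrong near the 0°/360° wrap;
  use the circular mean for hue distributions that straddle it.
* The GLCM is computed on the quantized gray sub-image restricted to the
  mask; background pixels never pair, but bins are fixed over [0, 255]
  rather than adaptive, so very dark regions concentrate in few bins.
* Tamura windows extend past the mask near the boundary and see zeroed
  background; coarseness is therefore comparable between seeds of
  similar size but not an absolute texture scale.
* Touching seeds are merged by design; the capture geometry is assumed
  to keep them apart.
* The perimeter estimator is tuned for convex-to-mildly-concave blobs;
  deeply fractal boundaries would be underestimated.
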