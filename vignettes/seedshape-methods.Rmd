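---
title: "Quantifying seed shape with geometric models and the J index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed shape with geometric models and the J index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 3)
library(seedshape)
```

## The method

Classical descriptions of seed shape ("reniform", "dorso plana",
"dorso canaliculata") are descriptive rather than analytical.  This
package implements the analytical alternative: a seed silhouette is
compared with a geometric figure defined by an algebraic equation, and
the similarity is quantified as the **J index**,

$$J = \frac{S}{T} \times 100,$$

where $S$ is the area shared by the seed mask and the model mask after
superposition for maximum coincidence and $T$ is the area of their
union.  $J = 100$ means pixel-for-pixel coincidence; values above 90
are conventionally read as a good adjustment of the model to the
species.  Because $J$ is a ratio of areas of the superimposed figures,
it is invariant to placement, orientation and size: what it measures is
*shape*.

In dorsal view, seeds split into two classes.  A region is **convex**
when the straight segment joining any two interior points stays inside
it; non-convex dorsal outlines carry a channel along the back that
shows in silhouette as a waist at mid-length and shallow notches at
the ends of the long axis.  The package ships nine reference models:
`DM1`–`DM4` for convex seeds and `DM5`–`DM9` for non-convex ones.

## The model registry

Three curve families cover the nine models (see `?dm_models`):

* `DM1` — the superellipse ("squared circle") $|3x/2|^3 + |y|^3 = 1$,
  with aspect ratio $3/2$.
* `DM2`–`DM8` — *two-arc* curves: an upper and a lower arc over a
  common abscissa interval $[-w, w]$,
  $$\mathrm{upper}(x) = h_u\sqrt{1 - |x/w|^p} - k_u\,g(x) + t\,x,
  \qquad
  \mathrm{lower}(x) = -h_l\sqrt{1 - |x/w|^p} + k_l\,g(x) + t\,x,$$
  with the quartic rational channel term
  $g(x) = 6/((x/\sigma)^4 + (x/\sigma)^2 + 6)$, normalized so
  $g(0) = 1$.  Convex models have $k_u = k_l = 0$ and close exactly at
  $\pm w$; channelled models ($k > 0$) close where the arcs cross,
  slightly inside $\pm w$, and the enclosed region is where
  $\mathrm{upper} \ge \mathrm{lower}$.  The exponent $p$ controls how
  square the ends are ($p = 4$ gives the flat-ended outlines of `DM5`
  and `DM6`).
* `DM9` — the polar curve
  $\rho(\theta) = (\cos^{20}\theta + 4\sin^2\theta)^{-2/3}$, an
  elongated outline with a mid waist and notched ends.

### Provenance and calibration of the two-arc coefficients

`DM1` and `DM9` are transcribed directly from their published
equations.  The published renderings of the `DM2`–`DM8` equations are
typographically corrupted (radical signs and fraction bars are lost in
the available text), so these models are *reconstructions*: the
two-arc structure, the per-arc coefficients, the shared quartic
channel denominator and the linear term of `DM4` follow the printed
skeleton, while the ambiguous numeric coefficients were calibrated
once against the published per-species morphometry and then frozen.
The calibration gate was: each model must rasterize into its declared
convexity class (solidity gate at 0.97) and have an aspect ratio
matching the mean of the species it describes (about 1.44, 1.47 and
1.56 for `DM2`–`DM4`; 1.43, 1.69, 1.17 and 2.0 for `DM5`–`DM8`).
A literal reading of the corrupted equations fails this gate (for
example it renders the `DM5` channel with a depth of well under 1% of
the outline height, which classifies as convex, with an aspect ratio
near 1.07 against a species range of 1.43 ± 0.06).  Each model's
`provenance` field records whether it is transcribed or reconstructed.
Orientation is immaterial to fitting (rotation is optimized), so the
convex models are drawn with the long axis vertical and the
non-convex ones horizontal, following the polar equation of `DM9`.

```{r registry}
dm_model("DM5")
```

## Rasterization

`rasterize_model()` scales a model so its bounding-box height equals
`height_px` pixels and fills it even-touch: a pixel is foreground iff
its center lies inside the curve.  Row 1 of a mask is the top of the
figure; the rasterizer owns the flip from mathematical y-up
coordinates to raster row-down coordinates.  Rasterization converges:
the pixel-count area approaches the polygon area of a dense boundary
sampling as resolution grows (within 0.5% at a height of 400 px), and
halving the resolution changes at most ~2% of foreground pixels.

## Morphometry

`measure_mask()` reports the ImageJ-convention descriptors: area $A$,
perimeter $P$, major axis $L$, width $W$, aspect ratio $AR = L/W$,
circularity $C = 4\pi A/P^2$ and roundness $R = 4A/(\pi L^2)$.  Two
numerical choices matter:

* **Perimeter** is the arc length of the marching-squares boundary
  polygon (contour of the mask at level 0.5), smoothed by a 5-point
  circular moving average.  Raw pixel-edge counting overestimates the
  perimeter of smooth curves by up to 27%; with the smoothed contour a
  digital disk measures $C \approx 1$ (tests allow $[0.95, 1.02]$).
* **$L$ and $W$** come from the second-moment best-fit ellipse,
  rescaled so the ellipse area equals $A$ (the "fit ellipse"
  convention), not from Feret diameters.

Boundary irregularities (e.g. the colliculae of real seed coats)
increase $P$ and so depress $C$, while $R$ — which only sees $A$ and
$L$ — is essentially unaffected; this contrast is asserted in the test
suite with synthetic bumps (< 2% change in $R$).

`classify_convexity()` labels an outline convex when its solidity
(outline area over convex-hull area, both measured on the sub-pixel
contour) is at least 0.97.  The threshold deliberately tolerates a
small hull deficit so that surface protuberances, which occupy a small
fraction of the area, cannot flip the overall-shape label; it is
exposed as a parameter.

## Fitting: maximizing J over a similarity transform

`jfit()` optimizes the superposition that a human operator performs by
eye.  The transform has five components: translation $(t_x, t_y)$,
isotropic scale $s$, rotation $\varphi$ and an optional mirror flip.
Anisotropic or non-rigid warps are deliberately excluded — they would
inflate J and break comparability with rigid superposition.

1. **Initialization** (`initial_alignment()`): centroids are matched,
   $s_0 = \sqrt{A_{seed}/A_{model}}$, and the principal axes are
   aligned.  Both axis polarities and both mirror states give four
   candidate transforms.  A near-isotropic mask has no defined
   orientation; it is taken as 0 and logged.
2. **Refinement**: Nelder–Mead over $(t_x, t_y, \log s, \varphi)$ from
   the best two candidates (configurable), iteration cap 200 per
   start, convergence at about $10^{-3}$ on J.  The pixel-count
   objective is piecewise constant, so the optimizer maximizes a
   smoothed *soft* overlap (the model is resampled onto the seed grid
   with bilinear interpolation and the fractional coverages are
   min/max-combined); the *hard* thresholded J is tracked at every
   evaluation and the best hard J ever seen is reported.  The result
   therefore never falls below the initializer.  Scale is bounded to
   $[0.5, 2] \times s_0$ to prevent degenerate collapse.
3. The model is always resampled onto the seed grid (never the
   reverse), so seed pixel counts are identical across models and the
   per-model J values are comparable.

On small masks the optimizer is verified against an exhaustive grid
search over the transform; on synthetic seeds it recovers the
generating non-convex model in ≥ 90% of draws at 2% boundary noise,
with every cross-model mean J below the own-model mean J — the
synthetic analogue of the species-specificity of the non-convex
models.

```{r fit-example}
seed <- generate_seed("DM7", eps = 0.02, height_px = 110, rng_seed = 7)
f <- jfit(seed, models = paste0("DM", 5:9))
f
```

## Average silhouettes

`average_silhouette()` replaces a display-software recipe (stacking
semi-transparent layers and magic-wand-selecting the darkest region)
with a well-defined statistic: masks are pose-standardized
(`align_mask()`: centroid centered, principal axis vertical, heavier
half down, optional mirror canonicalization), stacked, and the pixels
covered by at least a fraction $\tau$ of the masks are kept ("where
most of the seeds coincide").  The default $\tau = 0.5$ reads
"most" as majority coverage; $\tau$ is exposed because the original
recipe's effective coverage level is not recoverable from its
description.  $\tau = 1$ gives the intersection of the stack,
$\tau \to 1/N$ the union, and silhouette area is non-increasing in
$\tau$.  Scale normalization is off by default (populations are
stacked at true scale); a population of 20–30 seeds is the intended
input, and the `n_min` guard (default 20) can be lowered for small
experiments.

## The synthetic seed generator

Real seed photographs are not required for any test: the generator
draws seeds whose ground truth is known.

* **Outline noise**: the model boundary is perturbed *radially* by a
  band-limited harmonic field (harmonics 4–12, Gaussian coefficients,
  normalized to standard deviation $\varepsilon \bar r$, default
  $\varepsilon = 0.02$).  The noise model targets outline-shape
  variation between seeds, not sensor noise.  All nine models are
  star-shaped about their centroid, so a radial perturbation with
  positive radii cannot self-intersect; if the radius would drop below
  $0.2\,\bar r$, $\varepsilon$ is halved and the damping is logged.
* **Colliculae**: optional narrow Gaussian bumps emulate surface
  protuberances for the $C$-vs-$R$ contrast.
* **Jitter**: each seed is rotated (±10°), scaled (0.93–1.07) and
  translated (±3 px) — the placement variation of a composed plate
  whose seeds were oriented by hand.
* **Reproducibility**: one integer seed drives a per-index substream,
  so seed *i* of a population is identical regardless of how many
  seeds are drawn.

Mean J against the generating model decreases monotonically in
$\varepsilon$.  What the generator does *not* emulate: lighting
gradients, shadows, texture inside the silhouette, touching seeds,
and real biological within-population shape drift; passing tests
demonstrate correctness of the machinery on controlled outlines, not
performance on any particular photographic archive.

`generate_plate()` composes masks into a grayscale plate (dark seeds,
light background, mild Gaussian noise, optional ruler-like bar on the
border) to exercise the segmentation path end to end:
`read_and_binarize()` (Otsu or fixed threshold) and `segment_plate()`
(connected components, minimum-area filter, optional border
exclusion).  Physical scale is always supplied explicitly
(`mm_per_px`); reading it from an embedded ruler is out of scope.

## Population statistics

`summarize_populations()` gives per-group mean, sd, min, max and the
coefficient of variation $CV = sd/mean \times 100$, the statistic used
to compare variability of size traits against shape traits.
`compare_groups()` runs a Kruskal–Wallis omnibus test (two-sided,
$\alpha = 0.05$) for three or more groups, with a two-sample Wilcoxon
fallback for two.  The published workflow's stepwise stepdown post hoc
is not restated anywhere in enough detail to re-implement faithfully,
so the package substitutes pairwise Wilcoxon rank-sum tests with Holm
correction and a compact letter display built by the insert-and-absorb
algorithm; the output contract — groups sharing a letter do not differ
at $\alpha$ — is preserved.  `model_affinity_matrix()` aggregates long
J tables into the species × model matrix of mean J that heatmaps and
clustering are built from (the clustering itself is outside this
package's scope).

## Problem sizes and runtime choices

The test suite and the acceptance script run entirely on synthetic
data at deliberately moderate resolutions: model rasters of 110–200 px
height, populations of 20–50 seeds per model, and a brute-force
optimizer cross-check on masks of at most 64 px.  These sizes were
chosen so the whole suite completes in minutes on one core while
keeping rasterization error well below the tolerances being asserted;
raising the resolution tightens, never loosens, the agreement.

## Known limitations

* The reconstructed `DM2`–`DM8` coefficients are calibrated, not
  transcribed; against a different archive of the same species the
  absolute J values may shift even though the machinery is unchanged.
* J is computed on pixel counts; at very low resolution (< ~40 px)
  quantization dominates and fits below that size are refused by the
  rasterizer's degeneracy guard.
* The similarity transform cannot compensate anisotropic growth;
  species whose dorsal outline differs from a model by pure stretching
  will score lower J by design.
* Letter displays from the Holm-corrected pairwise tests can be more
  conservative than stepwise stepdown procedures on the same data;
  group memberships, not exact p values, are the stable output.
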