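---
title: "Methods: wide-field redox imaging analysis for cancer organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-field redox imaging analysis for cancer organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgredox)
```

## The measurement problem

Patient-derived cancer organoids (PCOs) are 3D cultures grown from tumor
samples that preserve the heterogeneity of the source tumor. Drug response
can be read out non-destructively by autofluorescence ("redox") imaging of
the metabolic co-enzymes NAD(P)H and FAD on a standard wide-field
one-photon epifluorescence microscope. The per-pixel **optical redox
ratio**

$$\mathrm{ORR}_{i,j} = \frac{\mathrm{NAD(P)H}_{i,j}}
 {\mathrm{FAD}_{i,j} + \mathrm{NAD(P)H}_{i,j}}$$

maps the oxidation-reduction state of the sample; effective drug response
typically lowers both the ORR and the organoid growth rate over a 48-hour
course. Because each organoid responds individually, the unit of analysis
is the *tracked single organoid*, not the well: each organoid is followed
over the acquisition schedule {0, 0.33, 12, 24, 36, 48} h (20 min encoded
as 0.33 h) and normalized to its own pretreatment value.

`orgredox` implements the full analysis chain: registration, per-pixel ORR,
segmentation, tracking, quantification of 24 variables, longitudinal
mixed-effect modeling, and multivariate (PCA) subpopulation analysis —
together with a synthetic phantom generator that provides ground truth for
every stage.

## Registration and ORR

Frames within a well are aligned by integer-pixel rigid translation
maximizing the normalized cross-correlation, computed over the overlap
region only (no wrap-around). Shifts are estimated on the NAD(P)H channel
against the pretreatment frame and applied unchanged to the paired FAD
frame; the output is cropped to the rectangle covered by every shifted
frame, so areas that do not overlap across the series never enter the
analysis. Sub-pixel registration is deliberately not attempted: residual
drift stems from stage repositioning and the downstream features are
organoid-scale. Correlation is normalized by default (`method = "ncc"`);
plain zero-mean correlation is available as a config option. A peak NCC
below 0.2 flags the estimate `low_confidence`. Ties at the correlation
peak are broken by the smallest shift magnitude, then lexicographically by
`(dy, dx)`.

ORR pixels where both channels read zero are undefined and carried as
`NaN` — never coerced to 0, which would bias minimum statistics.

## Segmentation

Wide-field autofluorescence frames have a low signal-to-background ratio
(SBR, typically 2–3), so segmentation works on an edge-enhanced image.
`segment_frame()` applies, in order: median denoising (25×25 px);
Gaussian background estimation and subtraction (450×450 px kernel, blur
sigma = kernel/4); a 13×13 local standard deviation filter; 3-class Otsu
quantization of the edge image with the lowest class discarded (the two
upper classes are merged into foreground); removal of regions under
100 px; hole filling; erosion with a disk of radius 9; Chan-Vese
active-contour refinement (200 iterations, contraction bias −0.6);
h-minima watershed splitting of touching organoids; hole filling; 5×5
Gaussian edge smoothing of each region re-thresholded at 0.5; and a final
morphology filter keeping regions with area > 1000 px and circularity
> 0.4. Segmentation is independent per frame — temporal coupling is the
tracker's job. Connectivity is 8-connected throughout.

Numerical choices worth knowing:

* **Working-scale kernel scaling.** The kernel sizes are calibrated to
  full 2048×2048 acquisitions. On smaller frames (non-strict mode) the
  *geometry* kernels — median, standard-deviation and background — scale
  with `min(dim)/2048`. An unscaled median kernel alone would shift the
  boundary of a small organoid inward by roughly
  $k^2\kappa/6$ px ($k$ = kernel half-width, $\kappa$ = boundary
  curvature), a 6–12% area bias at the 512 px test scale. The erosion disk
  stays at 9 px because its role is suppressing noise specks, which are
  pixel-scale at any frame size; the active contour re-grows organoids
  from the eroded seed. `strict = TRUE` refuses to scale and reproduces
  the full-scale parameter set exactly.
* **Chan-Vese variant.** The refinement is a discrete pixel-flip
  region-competition scheme: boundary pixels are added or removed by the
  sign of $(I-c_{in})^2-(I-c_{out})^2+\nu$, with
  $\nu = \mathrm{bias}\cdot(c_{in}-c_{out})^2$. A negative bias lowers
  the effective threshold below the midpoint of the two region means, so
  the contour tends to grow outward to the dimmer organoid rim — that is
  the sign convention fixed here for "contraction bias −0.6". The contour
  evolves on the median-filtered, background-subtracted image and is
  initialized from the eroded mask. A 3×3 majority filter is applied
  every 10th iteration as a weak curvature penalty; applying it every
  iteration behaves like curvature flow and measurably shrinks convex
  regions (~1 px ring).
* **Detectability guard.** Otsu's method always splits, even a
  signal-free frame, and a filled percolating noise foreground can
  survive erosion. The ratio of the top Otsu class's mean edge response
  to the lowest class's mean is ~3 on pure-noise frames versus ≥ 20 for
  organoids at SBR ∈ [2, 3]; frames below `min_edge_contrast = 8` are
  declared organoid-free.
* **h-minima depth.** The watershed runs on the negated Euclidean
  distance transform with minima shallower than `hmin_depth = 5` px
  suppressed (the watershed tolerance). The value is exposed in the
  parameters; 5 px suppresses spurious minima at the organoid scale used
  here. Watershed output is forced to partition the input foreground
  exactly; rare unassigned pixels are attached to the nearest label.
* **Circularity / perimeter.** Circularity is the plain $4\pi A/P^2$,
  clipped at 1. The perimeter estimator is fixed and documented: the
  outer boundary is Moore-traced through pixel centers, simplified by
  Douglas-Peucker at tolerance $\sqrt{2}/2$ px (collapsing digitization
  staircases into chords), and corrected for the half-pixel offset
  between pixel centers and the region boundary with miter joins at
  corners up to 90° and round joins beyond. The estimator is exact for
  axis-aligned rectangles (a 10×10 px square gives perimeter 40, hence
  circularity π/4) and asymptotically exact for disks (a radius-50 disk
  scores ≈ 0.97). Isolated 1–2 px blobs fall back to the crack-edge
  count; they are always removed by the area filter anyway.

## Tracking

Segmented organoids are linked across frames by two-pass linear
assignment on their centroids (the unweighted mean of region pixel
coordinates). Detecting rendered Gaussian blobs at those same centroids
and re-finding them with a blob detector would be lossless, so the
package links centroids directly. Pass 1 matches detections
frame-to-frame, minimizing total squared displacement; links beyond
200 px are forbidden, and not linking a detection costs
`max_link_dist^2`, so any admissible link is preferred to a
birth/death pair. Pass 2 optimally matches track ends to later track
starts (gap closing) within 200 px and at most 2 skipped frames. The
assignment problems are solved exactly with a shortest-augmenting-path
Hungarian solver implemented in the package (no assignment solver is
available in the dependency stack) and verified in the tests against an
exhaustive enumeration oracle. Ties break deterministically by smaller
distance, then smaller source label. Track merges and splits are
disabled: merge-like events are surfaced by the truth-matching metric
rather than by the linker.

## The 24 variables

Per organoid and time point: mean, minimum, maximum and standard
deviation of ORR, NAD(P)H intensity and FAD intensity (12 metabolic),
computed over raw registered pixel values — no background subtraction, no
smoothing — with undefined ORR pixels excluded; and area, perimeter,
solidity, extent, eccentricity, circularity, min/max Feret diameter,
minor/major ellipse axis, convex area and equivalent diameter
(12 morphological). Definitions follow standard region-property
conventions: solidity = area / convex area (convex area counted as pixels
whose centers fall in the convex hull of the region's pixel corners);
extent = area / bounding-box area; eccentricity and axes from the
same-second-moment ellipse including the 1/12 px self-variance term;
Feret diameters by rotating calipers on the corner hull; equivalent
diameter $\sqrt{4A/\pi}$. Units are pixels (the native acquisition is
1.625 µm/px; conversion is left to the caller). Organoids whose region
touches the post-crop border at *any* time point are dropped as whole
tracks, because the longitudinal models need complete per-organoid
series.

## Longitudinal statistics

Two normalizations mirror the tracked versus pooled analyses:
organoid-level ($X_{post}/X_{pre,\,organoid}$) and well-level
($X_{post}/\overline{X}_{pre,\,well}$). Pretreatment rows are excluded
from modeling (their organoid-level value is 1 by construction). The
tracked analysis fits

$$Y \sim \mathrm{time} + \mathrm{treatment} +
  \mathrm{treatment}\times\mathrm{time} + (1\,|\,\mathrm{organoid}) + \varepsilon$$

with time categorical (no linearity assumption), a random intercept per
organoid, and AR(1) correlation of within-organoid residuals over the
ordered posttreatment time *index* (the schedule is unevenly spaced;
index-based AR(1) matches the cited implementation's semantics).
Estimation is REML via `nlme::lme`, tolerance 1e-8, with a warned ML
fallback. The pooled counterpart is the same fixed-effects model by
`nlme::gls` with the AR(1) structure but no random intercept. Group
means and pairwise treatment differences at each time point come from
estimated marginal means (`emmeans`) with Tukey adjustment; the
multiplicity family is the set of pairs *within one time point*
(across-time multiplicity is intentionally not adjusted, matching
per-time reporting). Percent differences are reported as
`(mean_A − mean_B) × 100` on the normalized scale. The model term named
"organoid" is implemented as the grouping factor of the random
intercept — the alternative reading (a 20-min covariate) is statistically
incoherent with a random-effect notation. Pairwise pretreatment
correlations of all 24 variables are Pearson with unadjusted p < 0.05
significance masks; constant variables are masked and logged.

`simulate_normalized_series()` generates data from exactly this model
(random intercept + AR(1) errors) for parameter-recovery, coverage,
type-I-error and power studies; the test suite uses it at 10–15 organoids
per group over 3–5 time points, 200 replicates for bias/coverage and 500
for the null, and 60 replicates for the tracked-vs-pooled sensitivity
comparison — sizes chosen so the whole suite runs on a laptop in a couple
of minutes while keeping Monte-Carlo error well inside the asserted
margins.

## PCA protocol

All 24 variables are z-scored *within each time point* (each time point's
own mean and SD — also at 24/48 h; the loadings alone are pretreatment).
Loadings are the right singular vectors of the standardized pretreatment
matrix with a deterministic sign convention (largest-magnitude entry
positive). Posttreatment data are standardized within their own time
point and projected onto the pretreatment loadings. Reports surface
PC1–PC2 only; `top_loadings()` ranks variables by the Euclidean norm of
their (PC1, PC2) loadings with name-order tie-breaks, and `ellipse_95()`
draws the bivariate-normal ellipse at the χ²(2 df) 0.95 radius
(coverage, not a confidence region). The biplot scale factor is
`max|loading| / max|score|`.

## The phantom generator

`generate_phantom_series()` renders what the pipeline is designed to see:
organoids as disks with a low-order radial Fourier perturbation (keeping
circularity above the 0.4 retention threshold), solid organoids with an
FAD-elevated core (core ORR < rim ORR) and hollow organoids the reverse
with a 1.25× brighter, rounder appearance (hollow organoids carry more
NAD(P)H and look spherical); a flat background with summed-channel SBR
drawn from [2, 3]; cumulative global stage drift; Gaussian read noise
plus an intensity-proportional shot term; and per-treatment trajectories
of area and ORR. The control trajectory ends at +10% area at 48 h (the
reported control growth); cyanide spikes the ORR at 20 min and declines
below baseline by 36 h; 2DG declines from 12 h; cisplatin responds only
late; paclitaxel grows until 24 h and then falls below control. Only the
control growth anchor is a published number — the treated trajectories
encode the reported qualitative timing of significance, with magnitudes
fixed once as generator design. Ground truth (label masks, tracks, true
area and mean ORR per organoid and frame) is emitted alongside; truth ORR
is computed from the rendered organoid *plus background light*, which is
what a non-sectioning wide-field measurement integrates and what the
pipeline can recover.

What the phantoms do **not** emulate: realistic point-spread functions or
scattering, Matrigel autofluorescence texture (the background is flat),
organoid shape change beyond isotropic growth, overlapping or merging
organoids, and focus drift. Passing the phantom studies therefore
demonstrates correctness of the algorithms under the stated imaging
regime (SBR, size, drift, noise), not performance on arbitrary real
cultures.

Default working scale is 512×512 with 6–10 organoids of radius 25–60 px
(scaled with frame size), which keeps full-pipeline tests in seconds;
intensities are arbitrary units by design since wide-field counts are not
exposure-normalized.

## Known limitations

* Integer-pixel registration only; rotation and scaling are out of scope.
* The segmentation working-scale mode scales geometry kernels
  proportionally — results at 512 px are not bit-identical to running the
  full-scale parameter set on a downsampled image (use `strict = TRUE`
  on full-scale data for that).
* The perimeter estimator is exact for axis-aligned rectangles and
  asymptotically exact for smooth convex shapes; strongly concave regions
  are handled but carry larger discretization error.
* `emmeans` degrees of freedom use the containment method for the mixed
  model and residual df for the GLS fit; small-sample p-values are
  accordingly conservative.
* The tracker is nearest-neighbour in squared distance with no motion
  model; it is validated for drifts well under the 200 px linking cap.
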