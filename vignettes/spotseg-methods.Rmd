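---
title: "Shock-filter gridding and local clustering for microarray spot segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shock-filter gridding and local clustering for microarray spot segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotseg)
```

## The problem and the model

A two-channel spotted microarray scan is a pair of co-registered 16-bit
grayscale images, one per dye (Cy3, Cy5). Spots sit on a near-periodic
lattice (pitch ~28 px here, diameter ~15 px), arranged in groups
separated by wide empty lanes. The quantity of interest per spot is the
background-corrected intensity ratio of the two channels; the obstacle is
that real spots have irregular contours, inner holes, weak or missing
signal, and the slide may be scanned slightly rotated.

`spotseg` treats segmentation as a 1-D problem wherever possible. All
structural information about the lattice lives in averaged luminance
profiles, and a hyperbolic shock filter

$$P^{t+1}(i) = P^t(i) - \operatorname{sign}(\Delta P^t(i))\,|\nabla P^t(i)|$$

with $\Delta P(i) = P(i+1) - 2P(i) + P(i-1)$ and the minmod gradient
$|\nabla P(i)| = \min(|P(i+1)-P(i)|,\,|P(i)-P(i-1)|)$ (applied only where
the one-sided differences agree in sign; the identity elsewhere and at
the endpoints) evolves each profile into a piecewise-constant function.
Its jumps sit at the inflection points of the initial profile, i.e. at
spot edges and at the centers of inter-spot gaps after averaging. The
scheme has two properties the package asserts as tests: piecewise-constant
profiles are exact fixed points, and no value ever leaves the initial
range (a discrete maximum principle) — the filter sharpens, it never
overshoots.

Assumptions worth stating: channels are pixel-aligned (same scanner
pass); the lattice is periodic up to ~1 px jitter; rotation is small
(default search ±5°); spots are brighter than their local background
(the dyes add signal); and a group's profile contains at least about
three spot pitches so the autocorrelation period is identifiable.

## Pipeline stages and the parameters that matter

**Enhancement.** $r = \log_2(p+1)$ then an affine stretch of the observed
range to $[0, 2^{16}-1]$. The transform is strictly monotone; it exists
to give profiles and the Otsu threshold a usable dynamic range, not to
define intensities. All reported features are medians of *raw counts*.
A consequence worth knowing: the stretch is anchored at the global
minimum and maximum, so a single extreme outlier pixel compresses the
scale for the whole slide; heavy-tailed additive noise should be clipped
upstream.

**Rotation.** The estimate maximises the variance of the binned
projection profile over candidate angles (a Radon-transform search),
coarse 0.25° scan refined to 0.05° (`rotation_step_deg`). Variance peaks
when spot columns project onto common bins. Correction is bilinear
interpolation about the image center, which smooths slightly; geometry
and features tolerate this because profiles are averaged and medians are
robust.

**Addressing.** Otsu binarization, then dilation with a disk of radius
`ceil(0.75 × pitch)` — large enough to fuse spots one pitch apart,
far smaller than the several-pitch inter-group lanes — then connected
components; blobs under 10% of the largest area are treated as artifacts.
A count mismatch against the configured layout is an error listing the
detected boxes; the pipeline falls back to an even geometric partition
with a warning and a per-spot flag.

**Gridding.** Profiles are computed on a Gaussian-smoothed image
(width `k = 3` px, `sigma = 5` px — effectively a gentle 3-tap kernel;
both config-overridable since they are tied to ~15 px spots). The shock
filter runs `t_f = 50` iterations; jumps larger than 30% of the mean
filtered profile (`min_step_frac`) are steps. Each spot column produces a
rising then a falling step, so borderlines are midpoints of each
falling→rising pair ("the gap between two spots"), plus the sub-image
bounds. The pairing convention matters: the alternative (rising→falling
midpoints) would place lines through spot centers. Non-alternating
sequences are repaired by dropping the weaker of two same-sign
neighbours.

**Per-spot borders.** Within a grid cell $(x_l, x_r)$, the tight borders
are the leftmost rising and rightmost falling jumps above
`thr = 0.30 ×` mean of the *shock-filtered* slice profile (the filtered
profile is what the border conditions are phrased in; the choice of
leftmost/rightmost maximises the enclosed area when several candidates
exist). Missing pairs are rebuilt by translating the nearest detected
pair by the integer multiple of the lattice period, read off the first
significant local maximum of the unbiased profile autocorrelation
(search limited to lags ≤ n/3; peaks must exceed 3.5 standard errors,
minimum 0.15, so white noise errors out rather than returning a lag).

**Ellipses and clustering.** The tight rectangle's inscribed ellipse
`E_F` approximates the spot; `E_E` (semi-axes +3 px, clipped to the cell
with a flag if the cell is cramped) separates it from the background
ellipse `E_B` inscribed in the cell. Ellipse membership is by pixel
center, making rasterization bit-exact. Pixels inside `E_E` are split
into low/high by 2-means independently per channel and the union of the
high clusters is the foreground. Two implementation decisions differ
from the obvious transcription and are deliberate:

* **Clustering operates on raw counts, not the enhanced scale.** K-means
  centroids are not equivariant under monotone transforms; on the log
  scale, dim edge and hole pixels sit closer to the bright centroid and
  leak into the foreground (measured on the synthetic annular fixtures:
  hole-pixel exclusion drops from ~0.95 to ~0.64). Raw-count clustering
  reproduces the intended behaviour — inner holes excluded, irregular
  contours followed.
* **The 2-means is solved exactly.** In 1-D the optimal two-cluster
  partition under the within-cluster sum-of-squares objective is
  contiguous in sorted order, so the global optimum is found by a prefix
  sum scan over all n−1 splits. This is the fixed point Lloyd iteration
  seeks, without initialisation or RNG, and it is bit-reproducible; the
  test suite checks equality with an exhaustive-search oracle. Ties in
  the objective break towards the larger background cluster.

**Features.** Medians of raw counts over foreground and background pixel
sets per channel; `F = F_u − B` floored at 0 with a flag. The regression
ratio is the OLS slope of red on green over all `E_B` pixels (red on
green so the slope is comparable to `r = R/G`; the intercept absorbs
background offsets), with its coefficient of determination as a quality
score. Both the clustered medians and the in-ellipse (`E_F`) medians are
reported; normalisation uses the clustered values. Lowess (Cleveland's
robust locally weighted linear smoother, 3 robustness iterations) is
applied in MA coordinates — `M = log2(R/G)` on `A = ½log2(RG)` with span
0.20 — the standard realisation of intensity-dependent dye-bias
correction; the fit is subtracted and `r' = 2^{M'}`. Up-regulation is the
strict rule `r' > 2`. Spots with fewer than 10 valid (R, G > 0) partners
skip normalisation with a warning.

## What the generator emulates — and what it does not

`generate_pair()` renders: a periodic lattice (pitch 28 px, radius 7 px)
in rectangular groups; per-spot Cy3 levels and true ratios (both
recyclable vectors); weak (amplitude ×0.15), missing, annular
(hole radius 0.45 × spot radius) and irregular (random half-plane
crescent) defects; additive background noise and multiplicative
(fraction-of-signal) noise; bright streak artifacts; a smooth dye bias
imposed on the Cy5 amplitude as a function of A; global rotation; and
16-bit quantization. Spot edges fall off as a radial logistic with scale
0.45 px, i.e. a 10–90% transition of ≈2 px, so profiles have well-defined
analytic inflection points. Ground truth (masks = pixels at ≥ half the
plateau, hole pixel sets, levels, ratios, defect labels, group boxes) is
exact, and output is bitwise deterministic per seed.

It does **not** model PMT saturation, comet tails, spatially correlated
background gradients, dust, or channel mis-registration. Passing tests
therefore demonstrate correctness of the algorithmic chain under
realistic geometry and noise, not robustness to every scanner pathology.

Two generator-level modelling choices deserve their rationale:

* **Up-regulation experiments use spread intensities.** If every spot
  shares one foreground level, all differential spots collapse onto a
  single isolated A value, and *any* MA-lowess — robust or not — absorbs
  the entire effect locally, because within that window the differential
  spots are the majority. This is an identifiability limit of MA
  normalisation, not an implementation artifact. Real slides span a wide
  intensity range, so the simulated calling experiment draws per-spot
  levels log-uniformly (10k–35k counts) and places up-regulated genes
  above twice the minimum amplitude; under those conditions the calls
  separate cleanly (normalised ratios ≈4 vs ≈1).
* **Problem sizes.** The test fixtures use 2×2 groups of 8×8 spots
  (256 spots, ~532² px) and 10×10 single-group slides for ratio
  experiments — the geometry of production slides at reduced scale,
  chosen so the full suite runs in well under a minute.

## Numerical choices, degenerate inputs, tie-breaks

* Coordinates are 0-based; u = column (x), v = row (y); rectangles are
  half-open. Step position i means the jump P(i) − P(i−1).
* `sign(0) = 0`: zero-curvature points are shock-filter fixed points.
  Profile endpoints are copied (one-sided derivatives undefined).
* Adjacent same-sign step detections (a jump smeared over two pixels)
  collapse to the largest jump of the run.
* Constant images: enhancement returns zeros with a warning; rotation
  estimation returns 0 with a warning — batch runs survive blank
  channels rather than aborting.
* Degenerate tight boxes (< 3 px) are replaced by a 3×3 minimum box and
  flagged; `E_E` clipped by the cell is flagged (`clipped_exclusion`) so
  the exclusion zone never eats the background annulus.
* A spot whose `E_E` pixels are constant in both channels is flagged
  `not_found`; features are NA. Negative background-corrected
  intensities floor at 0 with a flag; ratios are undefined (NA) when
  G ≤ 0.
* The pipeline draws no random numbers anywhere: repeated runs are
  byte-identical.

## Known limitations

* **Foreground-median bias under soft edges.** The 2-means foreground of
  a 15 px spot with a ≈2 px edge transition contains roughly 45%
  sub-plateau edge pixels. The median of that mixture is an order
  statistic taken below the plateau mode, so multiplicative noise shifts
  it low: at 5% noise the recovered F sits ≈4% below the rendered
  plateau (at counting-noise levels, ≲1%). This is a property of the
  estimator-plus-edge-model combination, visible in
  `scripts/acceptance.R` as `f_recovery_error_pct`; ratios are largely
  immune because both channels share the geometry, which is why the
  ratio-based results are unaffected.
* Min–max contrast anchoring is sensitive to single-pixel outliers (see
  above).
* Normalisation cannot distinguish dye bias from differential expression
  concentrated at one intensity; see the generator discussion.
* `E_B` is bounded by the grid cell only; halo bleed-over between
  nearly-touching spots is not modelled or corrected.
* Group addressing assumes groups are separated by lanes wider than the
  intra-group pitch; overlapping or merged groups trigger the geometric
  fallback.
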