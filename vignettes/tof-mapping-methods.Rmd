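---
title: "Mapping trees outside forests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trees outside forests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Trees outside forests (TOF) — homestead groves, field-boundary lines,
riparian corridors, plantations embedded in agricultural or urban land — are
routinely missing from national forest inventories, although in forest-poor
countries they can exceed the mapped forest area. `tofscape` implements a
national-scale TOF accounting pipeline built from openly available
10 m optical and C-band radar imagery plus a single-date interferometric
surface model:

1. **Compositing.** Multi-date optical scenes are reduced to a greenest-pixel
   composite; multi-date dual-pass radar scenes are temporally averaged in
   the linear power domain and inter-swath scan-line gaps in one pass are
   filled from the other.
2. **Classification.** Threshold windows on composite NDVI and on VH/VV
   backscatter are intersected, a manually delineated forest/elevated-terrain
   mask is removed, and clumps below a minimum patch size are sieved out.
3. **Patch structure.** Edge-connected patches are labeled and binned into a
   size-class distribution.
4. **Canopy height.** A bare-earth terrain model is interpolated from ground
   control points by inverse-distance weighting, differenced from the
   surface model, and restricted to the TOF mask.
5. **Calibration.** Plot-aggregated heights are calibrated against an
   independent reference canopy surface by ordinary least squares, with
   outlier screening, a minimum credible height, and a per-division
   percentile cap.
6. **Accounting.** Per-division areas, percentages, map comparisons,
   per-capita figures, and a stratified accuracy assessment with unbiased
   area estimates and 95% confidence intervals.

Because the real inputs are tens of gigabytes of satellite imagery, the
package ships a first-class synthetic-scene generator with known truth; the
full pipeline is exercised and tested end to end on those scenes.

## Classification model

A pixel is classified as tree where all of the following hold on the
composites:

* `0.3 < NDVI < 0.9` — photosynthetic but not saturated/noise; the NDVI
  bounds are *exclusive*, matching the way the window is conventionally
  stated as a strict inequality.
* `-14 dB <= VH <= -9 dB` — volumetric (canopy) scattering; bounds
  *inclusive*, as ranges are stated inclusively.
* `-8 dB <= VV <= -2 dB` — a co-polarized veto that removes bare/urban
  false positives.

The binary intersection then has the forest-exclusion polygons removed
(pixel-center rule) and is sieved: 8-connected clumps below 25 pixels
(0.25 ha at 10 m) are dropped. The order is fixed as fuse → exclusion →
sieve so that removing polygons can never resurrect a sub-threshold
fragment. Note a deliberate asymmetry: the *sieve* clumps with edge+corner
(8-neighbor) connectivity, while *patch analysis* clumps with edge-only
(4-neighbor) connectivity — the patch-structure definition is explicitly
edge-based, the sieve's "adjoining pixels" is read inclusively. Both are
configurable in `threshold_config()` and `label_patches()`.

SAR averaging happens on linear power, `10 log10(mean(10^(dB/10)))`, never
on dB values; by Jensen's inequality the dB-domain mean underestimates mean
backscatter, and the test suite asserts the difference. The scan-line fill
threshold (−25 dB) is far below any physical backscatter in scenes of this
kind, so only inter-swath gaps qualify; it is exposed in
`fill_scan_lines()`.

Greenest-pixel compositing selects, per pixel, the date of maximum NDVI and
carries *all* bands from that date; ties break to the earliest date, nodata
dates are ignored. Occluded (cloudy) dates simply lose the argmax — no
explicit cloud mask is applied, mirroring dry-season acquisition practice.

## Terrain and canopy height

The terrain model is inverse-distance-weighted interpolation of bare-ground
control points: `z(x) = sum(d_i^-p z_i) / sum(d_i^-p)`. Defaults follow the
common grid-tool convention (`power = 2`, all points in range); a cell
coinciding with a control point (distance < 1e-6 × pixel) takes its
elevation exactly, which makes the surface reproduce its inputs and avoids
a division by zero deterministically. The surface is a convex combination
of the contributing elevations, hence bounded by their range.

The *pipeline* default search radius is 300 m rather than all points. With
global support, distant points receive small but non-zero weight, and over
terrain with regional trends the surface is pulled toward the regional
mean. That residual error is spatially correlated and survives 1-ha plot
averaging, where it acts as an errors-in-variables term that attenuates the
downstream calibration slope. A radius of roughly six times the mean
control-point spacing (820 points on a 2.56 km × 2.56 km scene gives ~45 m
spacing) keeps the interpolation local; cells with no point in range are
left as nodata, the analogue of the elevated/closed-canopy areas that are
excluded from terrain modeling in practice.

Raw canopy height is `DSM − DTM` on tree pixels only. Negative differences
are retained at this stage and screened during calibration.

## Height calibration

Radar-derived surface heights underestimate canopy tops because the phase
center sits below the canopy surface; the pipeline models the distortion as
linear. Heights are averaged over 100 m × 100 m (1 ha) plots anchored at
the raster origin — plot placement is a free choice and origin anchoring is
the deterministic one — and only tree-mask pixels contribute. Plots whose
absolute raw-vs-reference difference exceeds twice the 99th percentile of
all differences are excluded as gross errors (geolocation failures),
then ordinary least squares fits `reference ≈ slope × raw + intercept`.
A straight line fitted by OLS is the simplest estimator consistent with a
linear penetration model; the reported MAE before/after quantifies the
improvement.

Applying the model enforces, in order: raw pixels ≤ 0 m are removed
*before* the transform; calibrated heights below the minimum credible
height (2.19 m, a constant of the calibration, config-exposed and not
re-derived) become nodata; surviving heights above the per-division 99th
percentile are clipped to it. The cap is computed *after* the
minimum-height filter, on surviving pixels — the alternative order is
defensible, but capping on screened data keeps the cap insensitive to the
mass of removed non-tree pixels. Pixels outside every division fall back to
a global percentile with a warning.

The reference canopy surface supplied to plot aggregation is the reference
surface model minus the *same* interpolated terrain model, as when two
surface models are differenced against one bare-earth model. Terrain error
is then common to both sides of the regression, which partially cancels in
the fitted slope; the parameter-recovery tests cover the complete loop.

## Stratified accuracy and area estimation

Validation points are stratified by division × mapped class. For strata *h*
with mapped-area weights `W_h` (summing to 1 over the assessed region) and
`n_h` points of which `n_h(m, r)` carry map label *m* and reference label
*r*:

* cell proportions: `p(m, r) = sum_h W_h n_h(m, r) / n_h`
* overall accuracy: `sum_c p(c, c)`; user's accuracy `p(c, c) / p(c, ·)`;
  producer's accuracy `p(c, c) / p(·, c)`
* unbiased area of class *c*: `A_total × p(·, c)`
* standard error: `sqrt(sum_h W_h^2 q_h (1 - q_h) / (n_h - 1))` with `q_h`
  the within-stratum proportion of reference class *c*
* 95% CI half-width: `1.96 × SE × A_total`.

With a single stratum this collapses to the binomial normal-approximation
interval, which the tests assert in closed form, and the half-width is
checked against a 10,000-replicate stratified bootstrap.

Each point's mapped label is the mask value at its cell; to absorb
geolocation error, a disagreeing point counts as agreeing if any cell
within a 10 m buffer carries the reference label. The buffer is applied
when tallying, upstream of the estimator.

One practical note established by the coverage experiments in the test
suite: when the map is nearly perfect, reference-class trees inside the
mapped non-tree stratum are rare events. A collapsed two-stratum national
design then sees expected counts below one, the within-stratum proportion
estimate is usually exactly zero with zero standard error, and the normal
CI undercovers. The division-by-class design with 500 points per class per
division spreads the sample and restores nominal coverage (97/100 measured
in the suite); this is a property of rare-event normal approximation, not
of the estimator.

## The synthetic-scene generator

`scene_params()` fixes the study conditions; the defaults are the ones the
tests and the acceptance script run under.

| parameter | default | meaning |
|---|---|---|
| `size`, `px` | 256 × 256, 10 m | 2.56 km × 2.56 km scene |
| `tree_fraction` | 0.15 | national-scale TOF proportion |
| `archetype_mix` | 0.40 / 0.35 / 0.25 | boundary lines / homestead blobs / riparian corridors |
| `optical_noise_sd` | 0.05 | per-date noise on the NDVI scale |
| `sar_speckle_sd` | 1.5 dB | per-date speckle-like noise, dB domain |
| `scanline_gap_fraction` | 0.02 | descending-pass stripe coverage |
| `dsm_noise_sd` | 0.5 m | surface-model noise |
| `dsm_bias` | slope 0.8, intercept 0 | canopy penetration of the surface model |
| `reference_bias` | identity | unbiased reference canopy surface |
| `optical_dates`, `sar_dates` | 6, 12 | dry-season optical series, year-round radar |
| `terrain_amplitude`, `terrain_base` | 5 m, 12 m | low-relief floodplain |
| `forest_fraction` | 0.05 | contiguous-forest block exercising the exclusion mask |

Design notes, and what the generator deliberately does *not* emulate:

* Optical bands are abstract red/NIR reflectances carrying an exact NDVI
  signal: class NDVI trajectories get Gaussian noise *on the NDVI scale*
  and are then converted to a constant-brightness band pair, so
  `compute_ndvi()` reproduces the noisy NDVI exactly. There is no
  radiative-transfer realism — the classifier touches NDVI only.
* Speckle is additive Gaussian noise in the dB domain, not multiplicative
  gamma in power. This is a simplification; it suffices to test that
  averaging happens in the linear domain, but it does not reproduce
  heavy-tailed single-look speckle statistics.
* Patch archetypes (lines 1–3 px wide, 3–10 px blobs, sinuous corridors)
  reproduce the qualitative skew toward sub-1-ha stands; their parameters
  are not calibrated to any real patch geometry and make no claim of
  realism beyond that skew.
* Scan-line stripes are vertical, full-height, 1–3 px wide at −30 dB — an
  unambiguous gap signal for testing the fill rule, not orbital geometry.
* The forest block is rendered tree-like in optical and radar imagery (so
  the exclusion mask has something to do) but carries no canopy in the
  surface model; the height stages are masked to the TOF extent, so forest
  canopy would never be read there.
* No incidence-angle effects, atmospheric correction, real cloud
  morphology, or reprojection distortion: synthetic grids are planar and
  equal-area. Real-data users must supply an equal-area grid.

Passing tests on these scenes demonstrate that the *algorithms* are correct
under the stated noise model; they do not demonstrate that the fixed
threshold windows generalize to any particular real landscape, where class
distributions overlap the windows far more than the generator's do.

## Numerical choices

* NDVI with a zero denominator (both bands 0) is nodata; nodata propagates
  through every pixelwise operation.
* Greenest-composite ties break to the earliest date.
* IDW coincidence tolerance is 1e-6 × pixel size.
* Patch size classes partition (0, 10^5] ha with bins (0,1], (1,5],
  (5,10], (10,100], (100,1000], (1000,10^4], (10^4,10^5] — lower-exclusive,
  upper-inclusive.
* Percentage columns are reported unrounded; rounded columns sum to 100
  within 0.15, which the tests assert.
* Map-difference percentages use the comparison map (second argument) as
  the denominator; each reported comparison states its denominator.
* Division polygons must partition the extent; overlapping divisions are
  rejected rather than resolved.
* Rasters are written as 32-bit float TIFF with a JSON sidecar carrying the
  geotransform, CRS tag, nodata sentinel and value scale/offset.

## Problem sizes used in the tests

The suite runs the full pipeline on 256 × 256 scenes at 10 m — a 1/10-scale
terrain campaign (820 fitting points, 40 holdout) against the national
campaign's 8,200/400 — with 500 validation points per class per division
for the accuracy design, 10-seed replication for the noisy classification
and calibration-recovery properties, 10,000-replicate bootstrap for the CI
cross-check, and brute-force oracles (flood fill, direct-sum IDW) on grids
up to 64². These sizes were chosen so the whole suite exercises every stage
at meaningful sample sizes while remaining quick to run routinely.

## Known limitations

* Thresholds are fixed, manually defined windows; no supervised learner is
  provided, by design.
* The terrain model is IDW only — no kriging or splines; rapidly changing
  slope should be excluded via the same polygon mask as continuous forest.
* Calibration is a single national line; no per-division or per-canopy-type
  calibration.
* The temporal mismatch between an extent map and an earlier surface model
  is acknowledged, not modeled.
* Vector support is minimal (single-ring planar polygons); there is no
  general GIS geometry engine behind it.
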