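---
title: "Methods: shallow-water habitat mapping and change detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shallow-water habitat mapping and change detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seagrassmapr)
```

## The model and its assumptions

The pipeline treats a shallow coastal water column as a single
exponentially attenuating layer over a reflective bottom. The at-surface
reflectance observed in band $\lambda$ over depth $Z$ is

$$R(\lambda) = R_\infty(\lambda) + \left(R_b(\lambda) -
R_\infty(\lambda)\right)\, e^{-2 K_d(\lambda) Z},$$

where $R_b$ is the bottom reflectance, $R_\infty$ the reflectance of an
infinitely deep column, and $K_d$ an *operational* attenuation coefficient
for the combined downwelling and upwelling streams. The model assumes a
vertically homogeneous water column, a Lambertian bottom, and band-wise
independence; it ignores internal reflection at the surface and multiple
scattering between bottom and surface. Inverting it for $R_b$
(`correct_water_column()`) amplifies the signal — and any sensor noise —
by $e^{+2K_d Z}$, which is why an optically deep mask is applied *before*
inversion: pixels deeper than the site limit carry no measurable bottom
signal and the exponential should never be evaluated there. (Masking after
correction would yield identical values on surviving pixels; masking first
is numerically safer.)

Bathymetry comes from the blue/green band ratio. The working assumption is
that $x = \ln(R_{rs}(475)/R_{rs}(555))$ varies with depth but is nearly
invariant to the bottom type, so a site-calibrated quadratic
$Z = a_2 x^2 + a_1 x + a_0$ can be fitted to a few dozen in-situ depths
and applied per pixel. The radiometric conversion $R_{rs} = tR/Q$ is
applied literally with $R$ at the water surface: $Q$ is strictly defined
just beneath the surface, but no sub-surface conversion is added — the
ratio's calibration absorbs the constant factor anyway (it cancels in
$x$'s dependence on depth up to an additive constant).

Classification is a random forest over the three $R_b$ bands only — no
depth, texture or contextual features — so the classifier sees exactly the
physical quantity the correction is meant to restore. The forest is
implemented in the package (CART trees, Gini impurity, bootstrap
resampling, majority vote) rather than wrapping an external library, both
because no RF implementation is available in the target runtime and
because the classifier is the analytical core of the method; its contract
(100 trees, 2 random features per split, deterministic under a seed) is
pinned by tests.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `Kd` | 0.067, 0.078, 0.134 | m⁻¹ | operational site values per band (475/555/658 nm) |
| `R_inf` | 0.033, 0.024, 0.017 | – | deep-water polygon means per band |
| `t` | 0.54 | – | air–water transmittance (standard value) |
| `Q` | π | sr | Lambertian upwelling irradiance-to-radiance ratio |
| `mask limit` | 16.5 | m | optically deep limit of the site |
| SDB polynomial degree | 2 | – | site practice; quadratic in the log-ratio |
| smoothing window | 5×5 | px | low-pass on predicted depth to suppress pixel noise |
| `n_trees` | 100 | – | operational choice; more trees did not help |
| `n_random_features` | 2 | – | of 3 bands, per split node |
| sensor noise SD | 0.002 | reflectance | synthetic-scene noise level |
| within-class spectral SD | 0.005 | reflectance | within-meadow variability of bottom spectra |
| points per class | 50 + 50 | – | train + validation, balanced by design |
| depth points | 46 (32 + 14) | – | calibration + validation split used site-side |

## What the synthetic generator emulates — and what it does not

`simulate_scene()` builds the world the analysis assumes: a smooth
shore-to-deep gradient spanning 0.8–18.9 m with correlated local relief;
four benthic classes in contiguous patches whose priors follow depth
(*C. nodosa* centred near 5.8 m, *P. oceanica* near 8 m, rocky algae in
the shallows, sand depth-neutral); per-pixel bottom spectra drawn around
class means (sand brightest, *P. oceanica* darkest — dark enough that its
shallow canopy can mimic deeper water, the classic confounder the
bathymetry step must survive); the exact forward attenuation model; and
additive Gaussian sensor noise clipped to $[0,1]$. Ground truth is sampled
uniformly without replacement inside class masks, train and validation
disjoint by construction, optionally in opposite halves of the grid to
mimic a spatially split campaign.

It deliberately does **not** emulate: atmospheric or sunglint residuals,
sensor point-spread and adjacency effects, spatially correlated sensor
noise, sub-pixel class mixing, within-scene variation of $K_d$, tides, or
seasonality. A green end-to-end test therefore establishes that the
*algorithmic chain* is self-consistent under its own physics — not that
the defaults match any particular site's radiometry. The default class
spectra are plausible stand-ins, not calibrated measurements.

One property of the stated world deserves emphasis: the four default
spectra have blue/green ratios between 0.60 (*P. oceanica*) and 1.11
(sand). That *violates* the constant-ratio assumption of band-ratio
bathymetry on purpose — real benthos does too — so the synthetic SDB is
realistically imperfect (validation RMSE of 2–3 m, like the real
product) rather than artificially exact, and the downstream
classification inherits a realistic depth-error burden. The acceptance
suite measures the consequence: with satellite-derived depth the full
pipeline recovers roughly the mid-to-high-80s percent overall validation
accuracy across seeds (the fixed 90% bar in the acceptance criterion is
met only on some seeds), while the same chain run with the true depth
raster classifies markedly higher (a substitution the pipeline tests
exercise) — the gap is the band-ratio violation, not a defect in any
stage.

## Numerical choices

- **Out-of-range inversions.** $R_b$ outside $[0,1]$ (deep or noisy
  pixels) is counted and, by default, clamped; a `mask` mode drops the
  pixels instead. The count is exposed as an attribute so a pipeline log
  can report it.
- **Negative depth predictions** clamp to 0 m with a count; the quadratic
  can dip below zero outside the calibrated ratio range.
- **Smoothing** is a mask-aware uniform filter with reflect padding:
  masked pixels neither receive nor contribute values, and the map does
  not shrink at its edges.
- **Point-on-raster lookup** uses the nearest pixel centre with half-open
  pixel boundaries (a point on a left/top edge belongs to that pixel),
  stated explicitly so point-vs-raster comparisons are reproducible.
- **Tie-breaks.** Majority votes and arg-max label draws resolve to the
  lowest class code; training rows are sorted into a canonical order
  before seeding the forest, so training is invariant to input row order.
- **Truncation, not rejection,** for out-of-range spectral draws keeps
  the sample count deterministic.
- **Percent change** uses the earlier year as denominator, always; the
  alternative later-year convention can be had by swapping arguments, but
  is not the default.
- **Residual SD** of the depth fit is $\sqrt{SS_{res}/(n-p)}$ with $p$
  the number of coefficients, so it converges to the generating noise SD.

## Design choices where the design was open

- **File formats.** The runtime has no GeoTIFF-capable R package, so
  rasters use the Esri ASCII grid — a plain-text format GDAL and QGIS read
  directly — one file per band with a JSON sidecar for band/stage/legend
  metadata; configuration and manifests are JSON. The grid geometry,
  nodata and class tables survive round trips bit-exactly (tested).
- **Bathymetry sharing.** One depth raster, derived from a designated
  reference epoch (default: the last, closest to the in-situ campaign), is
  shared across all epochs; per-epoch bathymetry would conflate depth
  error changes with habitat change.
- **No re-derivation of $K_d$.** Attenuation coefficients and $R_\infty$
  are configuration inputs with operational defaults; estimating $K_d$
  from the imagery is out of scope.
- **Balanced training.** No class weighting or stratified bootstrap
  beyond balanced sampling (50 per class) — imbalance handling is the
  sampling design's job here, not the classifier's.

## Known limitations

- The analytical water-column model degrades where its homogeneity
  assumptions fail (turbid plumes, variable optical water types); the
  package has no per-pixel $K_d$.
- Band-ratio SDB carries bottom-type-dependent bias by construction; the
  5×5 smoothing trades local detail for stability.
- Accuracy statistics are plain ratios on point samples; no variance
  estimates or area-adjusted estimators are provided.
- Classification is purely per-pixel; no object-based post-processing or
  persistence filtering, so salt-and-pepper change artefacts are expected
  at patch boundaries.
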