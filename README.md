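# seagrassmapr

Interannual seagrass change detection from multispectral coastal imagery,
as a tested R pipeline. The package is aimed at coastal remote-sensing
scientists and habitat managers who map shallow Mediterranean benthos —
*Posidonia oceanica* and *Cymodocea nodosa* seagrass meadows, rocky algae
and sand — from high-resolution satellite reflectance, and who need the
whole chain (radiometry → bathymetry → water-column correction →
classification → accuracy → change) reproducible and unit-tested.

Because the original commercial imagery cannot ship with code, the package
includes a first-class synthetic-scene generator built on the same forward
radiative model, so every stage runs and is validated with no downloads.

## The model

The pipeline starts from atmospherically corrected at-water-surface
reflectance *R*(λ) on three visible bands (475, 555, 658 nm) and proceeds:

1. **Remote-sensing reflectance**: `Rrs = t·R/Q`, with air–water
   transmittance `t = 0.54` and `Q = π` sr (Lambertian).
2. **Satellite-derived bathymetry (SDB)**: the blue/green log-ratio
   `x = ln(Rrs(475)/Rrs(555))` is regressed against in-situ depth with a
   second-order polynomial `Z = a₂x² + a₁x + a₀`, applied per pixel and
   smoothed with a 5×5 low-pass filter.
3. **Optically deep masking** at the site limit `Z > 16.5 m`.
4. **Water-column correction** by the analytical optically-shallow model

       R(λ) = R∞(λ) + (Rb(λ) − R∞(λ)) · exp(−2·Kd(λ)·Z)

   inverted for the bottom reflectance `Rb`. `R∞` is estimated as the mean
   surface reflectance over a deep-water polygon; the operational
   attenuation coefficients default to `Kd = (0.067, 0.078, 0.134) m⁻¹`
   and `R∞ = (0.033, 0.024, 0.017)`.
5. **Random-forest classification** of the three `Rb` bands (100 trees,
   2 random features per split, Gini impurity, 50 training points per
   class), implemented in-package.
6. **Accuracy assessment** by error matrix (rows = predicted, columns =
   reference): overall, producer and user accuracies and Cohen's kappa.
7. **Change detection**: per-class areas (ha), signed percent change with
   the earlier year as baseline, OLS area trends over calendar years, and
   per-pixel gain / no-change / loss maps for each seagrass class.

## Worked example

```r
library(seagrassmapr)

spec  <- scene_spec(rows = 150, cols = 150, rng_seed = 7)  # 750 m x 750 m at 5 m
scene <- simulate_scene(spec)

rrs <- surface_to_rrs(scene$surface, spec$optics)
sdb <- estimate_bathymetry(rrs, scene$depth_points[1:32, ])
print(sdb$model)
#> <bathymetry_model> Z = +15.368*x^2 +16.7185*x^1 +6.09177*x^0
#>   n = 32, r^2 = 0.5781, residual SD = 3.294 m
validate_depth(sdb$depth, scene$depth_points[33:46, ])
#> $r_squared 0.937   $rmse_m 3.16   $n 14

rb  <- correct_water_column(apply_deep_mask(scene$surface, sdb$depth, 16.5),
                            sdb$depth, spec$optics)
rf  <- train_classifier(extract_features(rb, scene$train_points),
                        config = rf_config(rng_seed = 42))
map <- classify_scene(rf, rb)
accuracy_report(build_error_matrix(map, scene$val_points))
#> Overall accuracy: 88.0%   kappa: 0.840
#>         class producer_pct user_pct
#> 1   C. nodosa           74     82.2
#> 2 P. oceanica           98     89.1
#> 3 rocky algae           82     82.0
#> 4        sand           98     98.0
class_area(map)
#>   C. nodosa P. oceanica rocky algae        sand
#>     12.0350     17.4375     11.8175     14.9600
```

The numbers mean: the calibrated depth polynomial explains ~58% of the
calibration variance (bottom-type diversity perturbs the band ratio), the
smoothed depth map validates at RMSE ≈ 3.2 m on 14 held-out points, and the
full pipeline recovers the synthetic habitat map at 88% overall validation
accuracy — with the residual confusion concentrated, as in real imagery,
between the two spectrally similar vegetated classes. Areas are in
hectares over the 56.25-ha scene.

For a multi-epoch run (shared bathymetry from a reference epoch,
per-epoch classification and accuracy, area trends, gain/loss maps) see
`run_pipeline()` / `pipeline_config()`, or the command-line driver:

```sh
Rscript inst/cli/seagrass.R simulate --config spec.json --out scene/ --seed 3
Rscript inst/cli/seagrass.R run --config pipeline.json --out products/
```

## Vignette

`vignettes/methods.Rmd` documents the model assumptions, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, numerical policies (clamping, masking, tie-breaks), and known
limitations.
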