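# ringscale

Quantification of how the diameter of the budding-yeast bud-neck ring — the
septin ring and the actomyosin (contractile) ring that assembles on it —
scales with mother-cell volume.

In live-cell fluorescence microscopy, the ring diameter *d* is measured as
the full width at half maximum (FWHM) of a background-subtracted intensity
line profile taken along the ring, and mother-cell volume *V* is estimated
from the 2D segmentation mask by solid-of-revolution integration about the
cell's major axis. The scaling is summarized by an allometric power law,

    d = c · V^α,

fitted as a line in double-logarithmic space, with a case-resampling
bootstrap confidence interval for the exponent α and a residual comparison
against linear (d = a + bV) and logarithmic (d = a + b·log10 V) models. A
geometric null — spherical cells whose ring is a fixed fraction of the cell
diameter — predicts α = 1/3. The package is aimed at quantitative cell
biologists who want a tested, fully seeded implementation of this
measurement chain, plus a synthetic microscopy generator so every stage can
be validated without raw microscopy data.

## What is in the package

- **Synthetic scenes** (`population_config()`, `generate_population()`,
  `render_cell_frame()`, `render_cell_zstack()`, `generate_timecourse()`,
  `generate_aging_track()`): lognormal cell-volume populations of
  prolate-spheroid cells with ground-truth ring diameters, rendered as
  PSF-blurred frames, polarization-to-budding timecourses, replicative
  aging tracks, and confocal-like z-stacks.
- **Cell geometry** (`revolution_volume()`, `major_axis_length()`,
  `elongation()`, `total_cell_fluorescence()`, `reconstruct_volume_3d()`):
  mask morphometry and the hysteresis-threshold 3D validation route.
- **Ring measurement** (`detect_ring()`, `extract_profile()`,
  `smooth_subtract_background()`, `fwhm_diameter()`,
  `ring_total_intensity()`, `contour_ring_diameter()`, `measure_ring()`).
- **Cdc42-GTP cluster** (`cluster_threshold()`, `cluster_area()`,
  `cluster_axes()`, `cluster_contour_length()`,
  `local_curvature_radius()`): polarity-cluster size and local cell
  curvature at the incipient bud site.
- **Aggregation and statistics** (`aggregate_track()`, `normalize_aging()`,
  `deviation_ratio()`, `fit_power_law()`, `bootstrap_ci()`,
  `compare_models()`, `two_var_regression()`, `pearson_correlation()`,
  `binned_means()`, `run_measure()`, `run_fit()`).

The `analysis/` directory holds the workflow as numbered scripts
(`01_simulate.R` … `05_aging.R`), each a thin driver over the package that
writes its tables under `results/`.

## Worked example

Simulate a 60-cell steady-state population (volumes lognormal around 95 fL,
ground-truth exponent 0.31, 10% diameter noise), measure every rendered
frame, and fit the scaling models:

```r
library(ringscale)

pop   <- population_config(n_cells = 60, exponent_alpha = 0.31,
                           diameter_noise_cv = 0.10, seed = 1)
scene <- simulate_scene(pop, render_config(), frames_per_cell = 5)
tab   <- run_measure(scene, threshold = 200)
head(tab[, c("cell_id", "median_d_um", "median_volume_fL",
             "n_ring_frames", "accepted")], 3)
#>     cell_id median_d_um median_volume_fL n_ring_frames accepted
#> 1 cell_0001    1.484466        115.77035             5     TRUE
#> 2 cell_0002    1.468129         72.56722             5     TRUE
#> 3 cell_0003    1.833327        185.78340             5     TRUE

run_fit(tab, n_boot = 2000, seed = 1)
#> Power-law fit: d = 0.3473 * V^0.3059 (n = 60)
#>   95% bootstrap CI for the exponent: [0.2644, 0.3491] (2000 resamples)
#> Model comparison (n = 60), SSR in diameter space:
#>   power : d = 0.347 * V^0.306   SSR = 1.522
#>   linear: d = 1.088 + 0.00276 * V  SSR = 2.311
#>   log   : d = -0.577 + 1.020 * log10(V)  SSR = 1.495
#>   winner: log
```

The measured exponent (0.306, CI 0.26–0.35) recovers the generating value
0.31: each cell's diameter is read back off the rendered images by the
FWHM operator and its volume by revolution integration, so the fit
includes every measurement step, not just the statistics. The linear model
is clearly worse; at n = 60 the logarithmic model is numerically almost
indistinguishable from the power law over this narrow volume range (SSR
1.495 vs 1.522), and the two separate with larger samples — the 150-cell
run in `analysis/03_fit_scaling.R` selects the power law.

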