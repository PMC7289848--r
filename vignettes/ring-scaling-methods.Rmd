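---
title: "Measuring the scaling of the budding-yeast ring diameter with cell volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the scaling of the budding-yeast ring diameter with cell volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscale)
```

## The scientific question

In budding yeast, a septin ring assembles at the incipient bud site and
later scaffolds the actomyosin (contractile) ring at the bud neck. Unlike
symmetrically dividing cells, where the division-ring diameter is a direct
geometric constraint, the bud-neck ring diameter must be set de novo by the
self-assembly process. The quantitative question this package addresses is
allometric: how does the ring diameter *d* scale with mother-cell volume
*V*? The working model is a power law,

$$ d = c \, V^{\alpha}, $$

fitted as a straight line in double-logarithmic space. A purely geometric
null — spherical cells whose ring is a fixed fraction of the cell diameter —
predicts $\alpha = 1/3$; measured exponents below 1/3 indicate sublinear
size compensation. The package provides every stage needed to estimate
$\alpha$ from fluorescence microscopy: a synthetic scene generator with
known ground truth, cell-geometry morphometry, ring and Cdc42-cluster
measurement operators, per-cell track aggregation, and the scaling
statistics.

## The measurement model

**Ring diameter (line-profile method).** The ring channel is binarized at a
fixed per-dataset threshold; 8-connected components of at least 10 px are
candidate rings, and a moment-equivalent ellipse is fitted to the largest
one. A brightness profile is sampled along the ellipse major axis, 30 px on
each side of the center (60 px for very large-cell strains), each sample
averaging 10 bilinear samples perpendicular to the axis. After a 3-sample
gliding average and subtraction of the background (mean of the three
outermost samples per side), the diameter is the full width at half maximum:
the distance between the points where the profile first rises above half the
maximum, scanning inward from the ends. Two conventions here are
interpretations rather than published facts: the crossing search scans
inward from the profile ends (robust for double-peaked ring profiles), and
crossings are refined by linear interpolation between bracketing samples,
which removes a ±1 px quantization bias that would otherwise distort the
fitted exponent. The profile maximum is taken after background subtraction.

**Ring diameter (contour method).** At bud emergence the diameter is also
measurable along the cell contour: each of five frames centered on bud
emergence is smoothed with a 3×3 mean filter, sampled at the contour
vertices, averaged, and the diameter is the circular arc-length full width
at half maximum with the profile minimum as baseline.

**Cell geometry.** Volume uses solid-of-revolution integration: foreground
pixel centers are rotated into the major-axis frame (continuous rotation,
then 1-px binning, avoiding raster interpolation artifacts), and each 1-px
slice contributes a cylinder of diameter equal to the slice extent
(max − min + 1 px). Length is the major axis of the moment-equivalent
ellipse (normalized second central moments with the 1/12 unit-pixel term,
axis = 4√eigenvalue — the regionprops convention). Elongation is
$(\pi/6)^{1/3} L / V^{1/3}$, exactly 1 for a sphere and $(a/b)^{2/3}$ for a
prolate spheroid. A slice's width is its extent, so holes or concavities
within a slice are treated as filled; this is an assumption the published
wording leaves open. The independent validation route reconstructs volume
from confocal z-stacks by per-slice hysteresis thresholding (low threshold:
Li minimum cross-entropy iterated to 1e-6; high threshold: 90% of the
in-mask slice maximum); both thresholds are gain-equivariant, so the
reconstruction is invariant to illumination intensity.

**Cdc42-GTP cluster.** The cluster threshold is the median + 2 SD
(population SD) of in-mask intensities, computed per frame; the area is the
median suprathreshold pixel count over the three frames around peak
localization. Membership is "strictly above" and restricted to the cell
mask, which prevents bleed-through from neighboring cells — the published
analysis handled such artifacts by visual rejection, which the package
replaces with the mask restriction plus an explicit exclusion list. Cluster
size is cross-validated by a second measure: the arc length of the
suprathreshold run in a 65-vertex contour profile of the 5×5
maximum-filtered image (the max filter compensates the inward shift of the
cortical signal; it also widens the run by up to 2 px per side, a known
small bias of the published procedure). The local radius of curvature at
the bud site is a Kåsa algebraic circle fit to the 7 contour vertices
centered on the anchor — deterministic, exact on noiseless circles, with
the RMS radial residual reported for quality control.

**Aggregation.** All per-cell statistics are medians over the frames with a
valid ring detection; cells with fewer than 5 valid frames are rejected.
Aging records are normalized per mother to the first division
($d_\mathrm{norm} = V_\mathrm{norm} = 1$ at generation 1), and mutant
populations are compared through the deviation ratio
$d / (10^{b} V^{\alpha})$ against a reference fit $(\alpha, b)$.

## The synthetic scene generator

Because the raw microscopy is not redistributable, every stage is validated
against synthetic scenes with known ground truth. The generator emulates:

- **Populations**: lognormal volumes (default median 95 fL, log10 SD 0.25,
  spanning roughly 30–300 fL at ±2 SD — the pooled wild-type plus
  inducible-Whi5 range), prolate-spheroid shapes with truncated-normal
  aspect ratio (mean 1.2, SD 0.1, ≥ 1), and ring diameters
  $d = c V^{\alpha}$ (defaults $c = 0.34$, $\alpha = 0.31$) with
  median-preserving multiplicative lognormal noise (default CV 10%).
- **Frames**: the mask is the rasterized spheroid projection; the ring is a
  uniform-intensity bar of length $d$ across the neck, viewed edge-on, with
  linear sub-pixel edge coverage, convolved with a Gaussian PSF (σ = 1 px)
  on a constant background with Gaussian read noise (Poisson shot noise
  optional; the default is Gaussian-only so tolerance analysis stays
  deterministic). The bar model reproduces the plateau-shaped profiles of
  real rings and makes the analytic FWHM equal the bar length.
- **Timecourses**: a cortical cluster spot whose intensity peaks before bud
  emergence, followed by a ring persisting for a configurable number of
  frames, with per-frame ground truth.
- **Aging tracks**: mother volume growing linearly per generation (default
  7%/generation, reaching ~1.8× by generation 12) and diameters following
  $d_\mathrm{norm} = V_\mathrm{norm}^{\beta}$ (default β = 0.15).
- **Z-stacks**: spheroid cross-sections filled with cytoplasmic signal,
  blurred in-plane, for the hysteresis-reconstruction route.

The published work states no pixel calibration or intensity units, so the
defaults (0.1 µm/px; a.u. intensities with background 100 and ring
amplitude 500) are conventions, not reproductions; all are configurable.
What the generator does **not** emulate: phase-contrast image formation and
segmentation error, optical aberrations beyond a Gaussian PSF, bud-growth
mechanics, photobleaching, and focus drift. Tests passing on these scenes
therefore demonstrate correctness of the measurement and statistics
operators, not robustness to real segmentation artifacts.

Randomness is hierarchical: every cell and frame derives its own seed from
the scene seed through an avalanche hash, so enlarging a population never
perturbs earlier cells, and identical configurations are byte-identical.

## Statistics

The exponent is the OLS slope of $\log_{10} d$ on $\log_{10} V$. Its
confidence interval is a case-resampling percentile bootstrap over cells
(the unit of analysis is the per-cell median, so cells, not frames, are
resampled); the production default is 50,000 resamples, while simulation
studies in the tests use 2,000 for speed. Competing linear
($d = a + bV$) and logarithmic ($d = a + b \log_{10} V$) models are
compared by residual sum of squares evaluated in diameter space for all
three models — residuals of different models must share units — with the
power law's log-space SSR also reported. Two-variable regressions (e.g.
$d$ on $V^{1/3}$ and $L/V^{1/3}$) use OLS with an intercept and two-sided
t-based Wald p-values under homoscedastic normal errors, matching the
generalized-linear-fit routine conventional in this literature.

## Numerical choices and edge cases

- Absence of a ring detection is a value (`NULL` / invalid flag), never an
  exception; a profile whose signal touches an end is flagged invalid.
- Component area ties are broken by the lowest label in scan order;
  orientation is reported in [−π/2, π/2).
- The gliding average shrinks its window at profile ends so the
  outermost-3-sample background rule keeps its meaning.
- Li thresholding shifts non-positive intensities before taking logs and
  undoes the shift on return; the iteration stops at 1e-6 relative
  tolerance or when the two class means coincide.
- Contour profiles are circularly indexed; flatness is detected with a 1e-9
  relative tolerance so bilinear rounding cannot fake a peak.
- Collinear circle-fit vertices and rank-deficient regression designs raise
  errors rather than returning unstable estimates.

## Problem sizes and calibration design

The validation suite uses problem sizes chosen to make each property
measurable with modest Monte-Carlo error: the full-pipeline geometric null
renders 300 cells at 5 frames each; exponent-recovery calibration runs 100
replicate populations of 200 cells per generating exponent at the
generator level (the rendered route is exercised separately, since its
per-cell discretization error is shown to be well below the population
noise); bootstrap coverage uses 500 datasets of 100 cells with 2,000
resamples; deviation-ratio recovery renders 200-cell reference and mutant
populations, for which the median-ratio standard error (≈ 0.009) resolves
the programmed 16% offset.

## Known limitations

- The bar-shaped ring model has no hourglass or double-ring substructure;
  diameters during the septin-to-actomyosin transition are not modeled.
- The contour cluster length inherits the max-filter widening bias of the
  published procedure (up to ~2 px per side).
- The revolution volume assumes rotational symmetry about the major axis;
  strongly non-axisymmetric cells violate this by construction.
- Event frames (cluster peak, bud emergence) come from ground truth or user
  annotation; the package does not detect them.
- Deviation ratios depend on the reference fit being estimated on a
  population spanning the mutant's volume range; extrapolation beyond the
  reference range is not flagged automatically.
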