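Package: ringscale
Title: Scaling of the Budding Yeast Bud-Neck Ring Diameter with Cell Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for the allometric scaling of the septin
    and actomyosin (contractile) ring diameter with cell volume in budding
    yeast. Provides a synthetic fluorescence-microscopy scene generator with
    known ground truth (lognormal cell-volume populations, prolate-spheroid
    cells, bud-neck rings, cortical Cdc42-GTP clusters, timecourses, aging
    tracks, confocal-like z-stacks), cell-geometry morphometry
    (solid-of-revolution volume, moment-ellipse length, elongation,
    background-subtracted total fluorescence, hysteresis-threshold 3D
    reconstruction), ring measurement by line-profile full width at half
    maximum and by contour profiling, Cdc42 cluster quantification
    (threshold area, moment axes, contour length, local curvature radius),
    per-cell track aggregation, and a scaling-statistics layer (power-law
    fits with bootstrap confidence intervals, competing linear and
    logarithmic models, two-variable regressions, correlations, binned
    means).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
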