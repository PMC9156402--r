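Package: actopillar
Title: Actomyosin Pillar-Ring Contractility: Simulation, Force Inference
    and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolbox for micropillar-ring assays of
    reconstituted actomyosin cortices on soft hydrogel scaffolds. Implements
    a one-dimensional viscoelastic contractility model with load-dependent
    (catch-bond-like) myosin binding kinetics and a density-only control
    variant; Euler-Bernoulli cantilever mechanics for predicting pillar
    deflection profiles and inferring active forces from measured profiles;
    a slice-wise image pipeline that extracts per-pillar centrelines from
    confocal z-stacks by thresholding, watershed separation and
    intensity-weighted centroids; fluorescence standard-curve calibration
    for myofilament counting; model calibration to contraction trajectories
    with multistart nonlinear least squares; and seeded synthetic-data
    generators (trajectories, rendered pillar-ring stacks, calibration
    series) with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
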