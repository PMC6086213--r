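Package: boutonflux
Title: Longitudinal Axonal Bouton Plasticity: Simulation, Detection and
    Turnover Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying structural plasticity of axonal boutons in
    longitudinal two-photon imaging of mouse cortex. Provides a calibrated
    synthetic-cohort generator for bouton birth/death dynamics over a
    train-then-rest imaging schedule (day 0/4/8), a two-photon-like image
    renderer (anisotropic Gaussian point-spread function, motion artefacts,
    photon noise), bouton detection and alpha/beta size classification from
    intensity and width profiles along a traced axon, greedy longitudinal
    matching into formed/eliminated/maintained events, the standard per-segment
    turnover statistics (formation and elimination fractions, turnover rate,
    survival and stabilization), and cohort-level inference via Mann-Whitney U
    tests and nested linear mixed-effects models (genotype x phase with mouse
    and axon random intercepts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
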