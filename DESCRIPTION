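Package: localmfa
Title: Local Approaches for Isotopically Nonstationary Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation of mass isotopomer distribution (MID) dynamics
    on small metabolic networks with atom-transition maps, and three local
    estimators for isotopically nonstationary metabolic flux analysis
    (INST-MFA): kinetic flux profiling (KFP) from the exponential decay of the
    unlabeled fraction, nonstationary metabolic flux ratio analysis (NSMFRA)
    at converging network nodes, and a ScalaFlux-style subsystem estimator
    that fits analytic label-input functions by multi-start particle swarm
    optimization and estimates free fluxes by nonlinear least squares on the
    subsystem MID ODEs. Includes whole-process Monte-Carlo sensitivity
    analysis, a packaged synthetic network scenario, a small
    enrichment-difference failure-mode scenario, and a benchmark runner
    crossing methods with time-point counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    graphics,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
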