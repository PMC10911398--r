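Package: rrpkin
Title: Kinetics and Energy Landscapes of Synaptic Vesicle Priming and Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting patch-clamp observables from glutamatergic
    autaptic neurons (miniature EPSC rates, hypertonic-sucrose pulse responses,
    action-potential trains) into the rate constants of a one-pool model of the
    readily releasable pool (priming, depriming, and spontaneous fusion), and
    for comparing conditions in the energy domain. Includes an exact stochastic
    simulator of vesicle-pool trajectories rendered as realistic current traces,
    shot-noise variance-mean baseline correction for sucrose plateaus,
    back-extrapolation of cumulative evoked charges, Arrhenius energy-landscape
    assembly, and a saturating electrostatic charge-to-rate model of release
    triggering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
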