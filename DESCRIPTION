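Package: camapop
Title: Calcium-Modulated TRAIL Apoptosis in Heterogeneous Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action reaction-network modelling of extrinsic (TRAIL-mediated)
    apoptosis under elevated cytosolic calcium, as in Piezo1/Yoda1 signalling
    studies. Provides a general mass-action network container with a compiled
    derivative evaluator, stiff ODE simulation of single-cell trajectories with
    threshold event calls (cPARP apoptosis, MOMP via cytosolic Smac), Monte
    Carlo simulation of heterogeneous populations with normally distributed
    Bcl-2 and XIAP, ratiometric-calcium condition mapping, one-phase-decay
    dose-response fitting, and closed-form assay metrics (Yoda1 sensitization,
    donor-quenching FRET efficiency, ratiometric calcium summaries). Ships a
    synthetic, calibrated model of the calcium-TRAIL pathway plus seeded
    synthetic-data generators so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
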