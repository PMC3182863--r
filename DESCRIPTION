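Package: sarcomech
Title: Heterogeneous Half-Sarcomere Networks and Residual Force Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates skeletal muscle fibers as networks of mechanically
    coupled half-sarcomeres, each driven by a strain-dependent three-state
    cross-bridge cycle resolved over a discrete strain axis, an exponential
    passive elastic element, and a filament-overlap availability function.
    Half-sarcomere strength and passive stiffness vary across units via
    Gaussian multipliers, and series (optionally multi-myofibril lattice)
    force balance couples the units under imposed length trajectories.
    Provides ramp-and-hold versus isometric protocol pairs, the residual
    force enhancement (RFE) statistic, seeded heterogeneity ensembles,
    steady-state length-tension curves, and drivers for velocity, magnitude,
    length, and heterogeneity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
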