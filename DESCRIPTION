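Package: nfkbse
Title: Statistical-Ensemble Simulation of Heterogeneous NF-kB Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates extrinsic-noise-driven cell-to-cell variability in the
    IKK-IkB-NF-kB-A20 signaling network with a statistical-ensemble scheme.
    A mass-action ordinary-differential-equation model of the network is
    integrated with a fixed-step fourth-order Runge-Kutta scheme; ensembles
    of replicate cells are generated by Latin hypercube sampling of the
    kinetic rate constants from uniform intervals around reference values;
    nuclear NF-kB trajectories are summarized by six dynamic features and
    classified into four dynamic patterns; dose-response sweeps probe
    switching and hysteresis; and a heuristic coordinate search tunes rate
    constants so ensemble-average features match population-level targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
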