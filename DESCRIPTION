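Package: memtube
Title: Grand-Canonical Membrane Monte Carlo with Polymerizing Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for membrane tube formation driven by
    polymerizing semiflexible filaments. Implements a dynamically
    triangulated, periodically replicated membrane patch sampled by
    Metropolis and grand-canonical Monte Carlo (vertex insertion and
    removal controlled by a fugacity that maps to surface tension),
    discretized worm-like-chain filaments with sterically gated kinetic
    Monte Carlo (de)polymerization, and a reduced birth-death
    master-equation model of the single-filament bending transition with
    first-passage-time analysis. Includes observables for membrane tube
    pulling (radius, force-extension), height-fluctuation spectra,
    fugacity-to-tension calibration, filament bundle classification and
    alignment statistics, and mesh input/output in OFF, PLY and legacy
    VTK formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
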