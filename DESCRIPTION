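Package: evapKMC
Title: Lattice-Gas Kinetic Monte Carlo Simulation of Evaporating Thin-Film Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the drying of thin films of particle (e.g. amino-acid)
    solutions with a three-dimensional lattice-gas Kinetic Monte Carlo model:
    Metropolis evaporation/condensation sweeps, particle random walks within
    the liquid, and a sigmoidal schedule that couples the effective chemical
    potential to the dried-substrate fraction, producing dual-scale cellular
    deposit patterns. Includes AFM-style morphology analysis of the dried-in
    patterns: height-map projection, connected-component grain statistics with
    minimum-size filtering, hole-size histograms and dual-scale gap detection,
    plus plain-text, TSV and PGM input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
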