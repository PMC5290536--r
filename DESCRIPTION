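Package: failrecov
Title: Failure and Recovery Dynamics on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact continuous-time stochastic simulation (Gillespie kinetic
    Monte Carlo) of a three-process failure-recovery model on networks, in
    which nodes fail spontaneously, fail under neighborhood damage when too
    few neighbors remain active, and recover spontaneously. Includes
    generators for square lattices, random regular graphs and spatially
    embedded networks with an exponential link-length distribution; the
    mean-field rate equations with stationary-state, stability, spinodal and
    cusp-point analysis; and protocols for hysteresis loops, phase-switching
    statistics, Fourier-based limit-cycle detection and simulation-based
    phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
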