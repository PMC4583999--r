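Package: lvcomp
Title: Lotka-Volterra Competition Dynamics of Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of winnerless competition between
    subnetworks of balanced spiking neuronal networks. Builds block-structured
    random networks with exact in- and out-degrees (a fixed-degree variant of
    the configuration model), simulates leaky integrate-and-fire dynamics with
    delta synapses, reduces spike rasters to population rate series, and fits
    the derived Lotka-Volterra mean-field model: the quadratic slaved-rate
    relation Y = a + bC + fD^2, fixed points and their stability, nullclines,
    a Lyapunov energy function and attractor-saddle barriers, dwell-time
    (life-time) statistics of metastable states, and state-dependent
    (multiplicative) noise estimation. A stochastic Lotka-Volterra surrogate
    generator with planted parameters supports validation of every analysis
    stage without spiking simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    signal,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
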