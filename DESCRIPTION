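Package: merkelsim
Title: Network Simulation of Branched Merkel-Cell Touch Afferents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates slowly adapting type I (SAI) tactile afferents as a
    network of spike-initiation zones, each a leaky integrate-and-fire unit
    driven by a cluster of Merkel cell-neurite complexes and coupled by
    antidromic resetting.  A quasi-linear viscoelastic skin surrogate
    (Mooney-Rivlin elasticity with a Prony relaxation series) converts
    ramp-and-hold indentation into strain energy density; a linear
    rate-sensitive transduction stage with smoothed Gaussian noise converts
    strain energy density into receptor current.  Includes gradient-free
    Latin-hypercube response-surface fitting of the transduction parameters,
    spike-train statistics (ramp/static firing rates, normalized interspike
    intervals, exponential displacement-response fits with extra
    sum-of-squares F comparisons), arbor morphometry (cluster skew,
    unit-moving and cluster fill-up surveys), synthetic target-response and
    arbor generators, and closed-form cable-theory checks that justify the
    point-neuron abstraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lhs,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
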