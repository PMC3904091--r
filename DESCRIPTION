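Package: stsnet
Title: Spike-Triggered Stimulation in Small Plastic Feedforward Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fixed-timestep simulator for small feedforward microcircuits of
    leaky integrate-and-fire neurons with alpha-function synapses, weight-
    dependent (Gutig-type) spike-timing dependent plasticity, correlated
    Poisson background drive, and closed-loop spike-triggered stimulation
    (STS). Builds augmented disynaptic feedforward pathway (aDFP) networks,
    runs equilibration and pre/peri/post intervention protocols (background
    rate steps and STS), and analyses the results through firing-rate and
    synaptic-weight time series, pairwise spike-train correlation, and
    blocked, binned distributions of pairwise differences in spike timing
    (DST). The integration core is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
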