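Package: modgate
Title: Modular Neuronal Network Simulation and Burst Propagation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two sparsely coupled clusters of Morris-Lecar neurons
    connected through modified Tsodyks-Markram synapses and analyses activity
    propagation between neuronal sub-populations. Provides the full
    multielectrode-recording analysis pipeline used for such preparations:
    activity-intensity conversion with a kurtosis-based noise threshold,
    network-burst detection, inter-cluster delay and transfer-probability
    estimation, long-term asymmetry, burst-pattern similarity and entropy,
    bimodality statistics, and propagation vectors, together with a
    synthetic-recording generator with known ground truth for validating
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
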