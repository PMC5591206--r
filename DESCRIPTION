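Package: spatplast
Title: Spiking Networks That Learn Through Spatially Decaying Synaptic Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time integrate-and-fire simulation of spatially embedded
    random neural networks that learn Boolean input-output rules through a
    supervised plasticity signal released at the output neuron and decaying
    with Euclidean distance. Provides network generation with exponentially
    distributed connection lengths, synchronous spiking dynamics with
    refractory periods and transmitter depletion, the distance-dependent
    weight-adaptation rule with critical-point initialization, a training
    loop for Boolean rules, hand-built reference motifs (including a purely
    excitatory XOR gate), and ensemble success-rate sweeps with binomial
    confidence intervals. The simulation core is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
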