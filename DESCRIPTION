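Package: vmnsim
Title: Spiking Network Model of Ventromedial Hypothalamic Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of spiking activity in the ventromedial
    nucleus of the hypothalamus (VMN). Implements a modified integrate-and-fire
    neuron with cumulative post-spike potentials (HAP, AHP, DAP), randomly
    connected excitatory networks with unreliable delayed synaptic
    transmission, Ornstein-Uhlenbeck modulation of the external input rate,
    spike-pattern statistics (interspike-interval histograms, hazard
    functions, index of dispersion across binwidths), a genetic-algorithm
    parameter fitter, and scripted in-silico experiments reproducing emergent
    network rhythm generation and bistability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
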