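Package: mstdpnet
Title: Autoencoder Learning in Spiking Networks via Mirrored STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-layer network of conductance-based leaky
    integrate-and-fire neurons in which feedforward synapses learn by
    additive spike-timing-dependent plasticity (STDP) and feedback synapses
    by its temporally reversed (anti-Hebbian) counterpart, so that the
    combined "mirrored STDP" rule approximates gradient descent on an
    autoencoder reconstruction loss. Includes ON/OFF Poisson rate encoding
    of image-like stimuli, synaptic-scaling homeostasis that drives hidden
    units toward a target lifetime activation rate, a trainer with periodic
    plasticity-off evaluation, and the associated reconstruction, sparsity
    and weight-symmetry metrics, plus synthetic stimulus generators (bars,
    blobs, strokes) for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
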