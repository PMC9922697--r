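Package: hrsnn
Title: Heterogeneous Recurrent Spiking Neural Networks with STDP Learning
Version: 0.1.0
Authors@R:
    person("HRSNN", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of heterogeneous recurrent spiking
    neural networks (HRSNN) for spatio-temporal classification. Provides
    leaky integrate-and-fire reservoirs with gamma-distributed neuronal
    heterogeneity, trace-based spike-timing-dependent plasticity (STDP)
    with per-synapse heterogeneous learning dynamics, distance-dependent
    probabilistic connectivity, temporal spike encoding of frame
    sequences (difference receptors, square-cosine latency coding,
    max-pooling), membrane-potential readout with a linear classifier,
    separation-property metrics (99 percent singular-value effective
    rank, average neuronal activation), and Bayesian optimization over
    parameter distributions using a Matern kernel on the Wasserstein
    metric with a Sinkhorn approximation. Includes a synthetic
    moving-object task generator and desk-scale experiment drivers for
    heterogeneity ablations, sparsity sweeps and limited-data studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
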