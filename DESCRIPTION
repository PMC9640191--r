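Package: voltcast
Title: Surrogate Neural-Network Models of Neuronal Membrane Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ground-truth biophysical simulation and neural-network surrogate
    modelling of neuronal membrane potential. Simulates Hodgkin-Huxley
    point neurons and passive cable chains driven by alpha-synapse event
    trains, converts the traces into windowed supervised datasets, builds and
    trains five multivariate time-series forecasting architectures (linear,
    nonlinear, deep, dilated-convolutional and CNN-LSTM stacks) with
    curriculum staging and early stopping, runs teacher-forced and
    closed-loop autoregressive forecasts, fits a five-parameter Izhikevich
    spiking head by derivative-free search, and simulates recurrent
    microcircuits of surrogate cells with Tsodyks-Markram short-term
    plasticity, including connectivity/excitation parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
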