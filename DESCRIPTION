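Package: epmodkit
Title: Surrogate Modelling and Bayesian Calibration for Cardiac Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predictive modelling of cardiac tissue electrophysiology
    at reduced computational cost. Provides a stochastic scenario generator and
    finite-difference solver for heterogeneous anisotropic two-dimensional
    diffusion on a square domain, a convolutional-recurrent (ConvLSTM) surrogate
    that forecasts the diffusing field and exposes a latent representation from
    which the hidden physical parameters (diffusivities, scar boundary
    orientation and location) are regressed, and an approximate Bayesian
    computation sequential Monte Carlo (ABC-SMC) engine that calibrates a
    Hodgkin-Huxley-type fast sodium channel model against simulated patch-clamp
    summary curves with full posterior uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    pracma,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
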