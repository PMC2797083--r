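Package: oscnet
Title: Noisy Coupled Oscillator Networks: Simulation, Synchronization
    Bounds, and Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates diffusively coupled networks of noisy nonlinear
    oscillators (FitzHugh-Nagumo, Hindmarsh-Rose, time-varying linear)
    with the Euler-Maruyama scheme and quantifies the collective
    enhancement of precision: how gap-junction-like mutual coupling
    protects the individual units and their population mean from
    intrinsic noise.  Provides stochastic-contraction synchronization
    bounds with their eigenmode derivation, a Taylor-remainder bound on
    the nonlinear distortion of the population mean, a model-based
    nonlinear state observer that certifies closeness to noise-free
    behavior, spectral diagnostics (FFT power spectra, harmonic
    matching), quorum-sensing mean-field network reformulation,
    probabilistic network generators, and config-driven experiment
    presets.  All results are tibbles designed for pipe-based analysis,
    with broom-style tidy()/glance() and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
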