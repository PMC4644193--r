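Package: fdfluor
Title: Frequency-Domain Fluorescence Lifetime Analysis via Analog Filter Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Treats fluorescence decay as a cascade of analog low-pass filters:
    forward models of single- and multi-exponential fluorophores and three-level
    systems under arbitrary periodic excitation (sine, biased cosine, square
    wave, duty-cycle pulse train / frequency comb), closed-form time-domain
    responses obtained by residue inversion, a brute-force convolution and ODE
    oracle, an FFT-based digital lock-in that extracts per-harmonic phase delays
    and modulation ratios from sampled driver/response waveforms, assembly of
    multi-fundamental sweeps into a single phase-frequency curve, and nonlinear
    least-squares recovery of lifetimes and fractional amplitudes from such
    curves. Includes a seeded synthetic-acquisition generator emulating the full
    driver-fluorophore-detector chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    readr,
    jsonlite,
    ggplot2,
    deSolve,
    stats,
    utils,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
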