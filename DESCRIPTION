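Package: tdaf
Title: Time-Dispersion Analysis of Features for Plant Electrome and Turgor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window complexity analysis of plant electrophysiological
    (electrome) recordings and leaf turgor (patch-pressure) series. Cuts long
    single-channel voltage time series into overlapping sub-minute windows,
    computes approximate entropy, detrended fluctuation analysis scaling
    exponents and Welch band-integrated spectral power per window, and pools
    the per-window features into time-indexed bins whose dispersion
    (min/quartiles/median/max) is compared before versus after a stimulus.
    Includes seeded generators of synthetic electrome and turgor series with
    stimulus-response structure (colored-noise baseline, superposed voltage
    spikes, post-stimulus slow-wave regimes, turgor oscillations with
    controlled coefficients of variation) for testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
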