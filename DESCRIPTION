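Package: aperiodica
Title: Simulate and Compare Measures of Aperiodic Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating neural field signals with controlled
    aperiodic (1/f power-law or synaptic-knee) and periodic (stationary or
    bursty oscillation) structure, and for computing and comparing the
    time-domain and frequency-domain measures commonly used to quantify
    aperiodic activity in electrophysiological recordings. Time-domain
    measures include the autocorrelation and its decay time, detrended
    fluctuation analysis, rescaled-range Hurst exponent, Higuchi, Katz and
    Petrosian fractal dimensions, Hjorth parameters, Lempel-Ziv complexity,
    and approximate, sample and permutation entropies. Frequency-domain
    measures include Welch spectral estimation, direct log-log line fits
    (OLS, robust, RANSAC, exponential, with optional alpha-band exclusion),
    iterative spectral parameterization with Gaussian peak removal (fixed
    and knee forms), and irregular-resampling auto-spectral analysis
    (IRASA). An evaluation harness runs measure batteries over simulation
    grids and computes error statistics, Spearman correlation matrices,
    bootstrap confidence intervals and difference tests, and semi-partial
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    minpack.lm,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
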