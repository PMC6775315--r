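Package: cgmfractal
Title: Complexity and Fractality Analysis of Continuous Glucose Monitoring Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the complexity and fractal structure of
    continuous glucose monitoring (CGM) records. Implements alpha-stable versus
    Gaussian fitting of glucose increment magnitudes with quantile-quantile
    diagnostics, spectral exponent estimation by the lowPSD_we procedure with
    conversion to a Hurst exponent, multiscale sample entropy, and multifractal
    detrended fluctuation analysis with the multifractal spectrum width, plus an
    ordered-subsequence bootstrap for error bars and a two-period comparison
    pipeline. A synthetic-data module (fractional Gaussian noise and Brownian
    motion via exact circulant embedding, binomial multiplicative cascades,
    alpha-stable increments, CGM-like traces) provides analytic oracles for
    every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
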