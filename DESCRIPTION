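Package: plumecorr
Title: Spectral Correlation Analysis and Fisher Information for Multisource Odour Plumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, frequency band by frequency band, the Fisher
    information that correlations between two odour-concentration
    timeseries carry about the spatial separation of their sources.
    Provides windowed trigonometric decomposition of concentration
    signals into per-harmonic correlation components, pooled
    bivariate-Gaussian statistics of the Fourier coefficients across
    source pairs, asymmetric-Laplacian / Gamma / generalized inverse
    Gaussian models of the correlation components (with optional
    intermittency, fitted by expectation-maximization and ranked by
    nested cross-validation), closed-form Fisher information with
    exponential-decay fits and bootstrap uncertainty, robust
    ("elbow") regression of information on frequency, a surrogate
    generator producing covarying multisource signals from prescribed
    covariance kernels, and integral length scales from velocity
    autocorrelation functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
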