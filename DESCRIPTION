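Package: erpdeconv
Title: Overlap-Corrected Regression ERPs by Sparse Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates event-related responses from continuous multichannel
    electrophysiological recordings by regression with linear overlap
    correction (deconvolution). Models are specified per event type with
    Wilkinson formulas supporting categorical predictors, linear covariates,
    and non-linear covariates via cubic B-spline, two-dimensional tensor
    spline, and cyclic spline bases. The instance-level design matrix is
    time-expanded into a sparse continuous-time design matrix under stick,
    temporal-spline, or truncated-Fourier bases, artifact intervals are
    detected by a moving-window peak-to-peak criterion and blanked from the
    design, and coefficients are estimated per channel with an iterative
    sparse least-squares solver (LSMR) or cross-validated elastic-net
    regularization. Includes a mass-univariate (no-deconvolution) twin fit,
    coefficient-to-waveform conversion with spline effect evaluation and
    baseline correction, plain-text import/export, and a synthetic-data
    simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    splines,
    mgcv,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
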