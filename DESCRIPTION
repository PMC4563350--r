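Package: gradsig
Title: Signal Extraction for Noisy Morphogen Gradient Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting the underlying signal from noisy
    one-dimensional gene-expression profiles such as the Bicoid
    anterior-posterior gradient in Drosophila embryos. Implements singular
    spectrum analysis (Hankel trajectory-matrix SVD with diagonal averaging
    and w-correlation separability diagnostics), fitting of the
    synthesis-diffusion-degradation exponential gradient model, and
    comparison extractors based on automatic ARIMA, fractionally integrated
    ARIMA, exponential smoothing state-space models, and feed-forward neural
    autoregression. Includes a reproducible Monte-Carlo benchmark that
    scores the extractors with RMSE, MAE, MAPE and relative RMSE, Wilcoxon
    rank-sum comparisons, unit-root and whiteness residual diagnostics, and
    signal-noise correlation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
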