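Package: rodeo
Title: Robust Expression Deconvolution of Bulk Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell type-specific gene expression profiles (the
    signature matrix S) from bulk expression data E and known cell type
    proportions C under the linear mixing model E = S * C. The core
    estimator fits, per gene, a no-intercept robust linear regression by
    Huber M-estimation (IRLS with MAD scale) and iteratively excludes
    cell types receiving negative coefficients, yielding non-negative
    expression profiles that are resistant to outlier samples. Ordinary
    and non-negative least-squares baselines, a ground-truthed pseudo-bulk
    simulator with batch structure and outlier samples, accuracy metrics
    (profile and per-gene correlations, RMSE), and sample-size and
    proportion-noise benchmarking sweeps are included, together with
    delimited-matrix readers/writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
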