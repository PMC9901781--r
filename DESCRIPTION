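Package: audimpute
Title: Validation of Imputation Models for Sparse Audiometric Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize structured missingness in pure-tone
    audiograms and to validate imputation models under realistic sparsity.
    Provides cleaning rules for cochlear-implant-candidate audiogram tables,
    sparsity profiling, structured amputation (mask generation under
    real-world, random, terminal and central removal distributions), six
    imputation model families (univariate statistics, within-audiogram
    interpolation, k-nearest neighbors with partial distances,
    chained-equation regression imputation, gradient boosted trees and a
    multilayer perceptron), pooled error metrics with confidence intervals,
    a repeated nested cross-validation assessment engine, and a calibrated
    synthetic audiogram generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
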