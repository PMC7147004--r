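Package: txclock
Title: Transcriptomic Aging Clocks and Exposure-Induced Age Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparse linear transcriptomic age predictors from
    multi-study log2 expression matrices and quantifies exposure-induced
    aging acceleration as the residual of predicted minus chronological
    age. Provides moderated-t differential expression with
    Benjamini-Hochberg false-discovery-rate control, age-by-exposure
    overlap analysis (Venn counts, signed maximum fold change, first
    principal component loadings), LASSO feature selection by cyclic
    coordinate descent with 5-fold cross-validated lambda selection and
    ordinary-least-squares refit, two cross-validation designs
    (random holdout and leave-one-study-out), per-group delta-age
    inference, and a multi-study expression simulator with planted aging
    trajectories, exposure effects, and batch structure for end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
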