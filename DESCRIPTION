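Package: nichecor
Title: Conditional Correlation of Gene Expression Across Cellular Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spatially co-regulated gene programs in single-cell
    spatial transcriptomics data while adjusting for the cell-type landscape
    and technical confounders. Aggregates expression over cellular
    neighborhoods (k-nearest, radius, or custom), computes the correlation of
    neighborhood expression conditional on neighborhood confounders via a
    Schur complement / residual-regression equivalence, extracts gene modules
    by thresholded Leiden community detection, scores modules per cell and
    per neighborhood with inverse-square-root gene weights, attributes module
    activity to cell types, and summarizes conditional correlation networks
    across multiple samples (consensus and inter-sample-variable gene pairs).
    Includes a synthetic data generator with planted spatial co-expression
    programs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    mclust,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
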