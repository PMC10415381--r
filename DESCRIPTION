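Package: umicoex
Title: Cell-Type-Specific Gene Co-Expression from UMI Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and testing of cell-type-specific gene co-expression
    networks from single-cell RNA-seq UMI counts. Observed counts are modelled
    as Poisson measurements of latent relative expression levels scaled by
    per-cell sequencing depth; first and second moments of the latent
    expression are estimated by iteratively re-weighted least squares, and
    pairwise independence is tested with an asymptotically standard normal
    statistic. Includes a Gamma-Poisson Gaussian-copula count simulator,
    permutation-based null data generation, normalization-based correlation
    baselines, two-group differential co-expression with a label-permutation
    test and module extraction, and evaluation metrics (attenuation factor,
    precision-recall, adjusted Rand index, subspace distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust,
    knitr
Config/testthat/edition: 3
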