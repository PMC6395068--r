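Package: smokefact
Title: Factorial Linear-Model Analysis of Smoke-Exposure Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-gene multivariable linear modelling of normalized
    expression matrices from factorial smoke-exposure designs
    (exposure x genotype x sex, at one or more exposure durations),
    with FDR plus fold-change significance calling, exposure-by-duration
    interaction testing, k-means and hierarchical clustering of response
    genes for heatmap export, a permutation-calibrated gene-set
    association score, hypergeometric and Fisher overlap enrichment,
    cross-duration effect-size comparison, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
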