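Package: embryomodes
Title: Collective Modes of Gene Expression in Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for embryonic transcriptomes of invariant-lineage
    embryos: robust, structure-constrained identification of cell types from
    single-cell expression posteriors; removal of known variance sources (gene,
    mother, embryo and cell-type means, developmental staging); permutation-null
    rank selection; detection of collective inter-cell variation by shuffle
    tests; maximum-entropy Gaussian models of cell-cell interactions fit by
    moment matching; L1-regularized sparse network inference with Schulze rank
    aggregation; and eigenmode decomposition of the model covariance into
    collective modes. Includes a synthetic-embryo generator with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
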