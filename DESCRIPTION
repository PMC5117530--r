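Package: stromasig
Title: Stability-Resampled Expression Signatures for Stromal Cell
    Transcriptomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives robust gene-expression signatures for mesenchymal
    stromal cells (MSCs) and related cell types from multi-batch expression
    compendia. Implements a resampling stability protocol around an
    empirical-Bayes moderated t-test (repeated 7-vs-7 subsampling with
    replacement, intersection of FDR-significant calls until a plateau, and
    median-rank aggregation), frozen-reference quantile/batch normalization,
    probe-union platform merging and probe-to-gene collapse, set-algebraic
    derivation of tissue-specific and lineage-core signatures,
    hypergeometric marker-panel enrichment, PCA and correlation-based sample
    clustering, thresholded Pearson coexpression networks with Cytoscape
    export, and population doubling-time statistics. A synthetic-data
    module generates expression compendia with planted differential
    expression, batch structure and marker panels, together with the ground
    truth needed for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
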