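Package: xmodnn
Title: Explainable Modular Neural Networks for Biomarker Discovery in
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and explains modular neural networks whose
    architecture mirrors a functional gene hierarchy (genes, pathways,
    pathway groups, top categories, output). Each hierarchy node is a
    small neural module with its own auxiliary classifier head; training
    uses a weighted multi-loss in which module layers are included
    progressively, and explanations are produced by epsilon-rule
    layer-wise relevance propagation, normalized per module layer and
    aggregated across a stratified cross-validation to flag biomarkers of
    exceptional relevance. Includes a synthetic-data generator with
    planted discriminative genes so the whole pipeline is testable
    without external cohort data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
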