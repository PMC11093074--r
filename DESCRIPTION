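Package: FuzzyFlows
Title: Fuzzy Expression-Level Flow Analysis for Grouped Single-Cell
    Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks how genes move between ordered expression levels
    (e.g. not-expressed, low, medium, high) across an ordered series of
    conditions. Per-(cluster x condition) pseudobulk profiles are
    fuzzified with triangular membership functions into graded level
    memberships; every level path across the condition series is a
    "flow" whose width is the summed gene membership, and flows matching
    a pattern predicate (such as a final level above all prior levels)
    yield membership-ranked gene lists and gene-set enrichment.
    Includes antibody-based cell calling for low-RNA populations
    (CITE-seq), UMI filtering, per-sample downsampling and pooling,
    expression-bin-matched module scoring, and a seeded negative
    binomial simulator with planted fold-change patterns for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, Visualization,
    GeneSetEnrichment
RoxygenNote: 7.3.3
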