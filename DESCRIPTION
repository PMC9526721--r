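Package: coexscreen
Title: Co-Expression Modules and Connectivity-Map Scoring for
    Signature-Based Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for in-silico small-molecule screening
    from two-group expression data. Provides expression-matrix import with
    sample quality control and quantile normalization, from-scratch weighted
    gene co-expression network analysis (soft-thresholded adjacency,
    topological overlap, average-linkage module detection, eigengenes,
    module-trait statistics, gene-set over-representation), up/down query
    signature extraction by differential expression, and Connectivity-Map
    build-02 style rank-based Kolmogorov-Smirnov connectivity scoring with
    permutation p-values, percent non-null, specificity and compound
    ranking. Closed-form preclinical metrics (sciatic function index,
    regenerating-axon estimates, pupillary constriction, qPCR fold changes)
    and seeded synthetic-data generators with ground truth are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'expression-io.R'
    'network.R'
    'signature.R'
    'connectivity.R'
    'preclinical.R'
    'simulate.R'
    'pipeline.R'
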