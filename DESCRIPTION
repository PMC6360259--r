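Package: pgcna
Title: Parsimonious Gene Correlation Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds sparse gene co-expression networks from time-course
    expression data by retaining only each gene's few strongest Spearman
    correlations, detects expression modules with a seeded ensemble of
    Louvain modularity clusterings, and characterizes modules by
    hypergeometric gene-signature enrichment, cross-network and
    differential-expression overlap statistics, and module expression
    dynamics (donor-median profiles, z-scores, fold changes versus
    baseline). Includes informative-probe selection and probe-to-gene
    merging for array data, GEXF/GraphML network export, a synthetic
    multi-donor time-course generator with planted modules for end-to-end
    validation, and a single-call pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    methods,
    SummarizedExperiment
Imports:
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    yaml,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'pgcna-package.R'
    'AllClasses.R'
    'accessors.R'
    'clustering.R'
    'dynamics.R'
    'enrichment.R'
    'io.R'
    'network.R'
    'overlap.R'
    'pipeline.R'
    'selection.R'
    'simulate.R'
    'utils.R'
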