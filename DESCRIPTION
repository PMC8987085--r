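Package: comberon
Title: Detection of Naturally Occurring Receptor Combinations from
    Single-Cell Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies naturally occurring combinations of co-expressed
    receptors ("comberons") in a chosen cell class from single-cell
    transcriptomics. Receptors are ordered along a Ward-linkage dendrogram of
    single-cell co-expression with optimal leaf ordering, scored by expression
    fraction, interaction-network enrichment of connections to differentially
    expressed genes (binomial test), and cross-species conservation of
    dendrogram neighborhoods; the normalized, smoothed combination of the
    three measures is scanned for peaks, and peak membership is quantified by
    bootstrap resampling of samples. Includes the statistical machinery for
    validating detected combinations (hypergeometric enrichment, permutation
    null of bootstrap frequencies, likelihood-ratio test of dendrogram
    distance, split-half comparisons), a two-dimensional ligand-by-receptor
    extension for intercellular communication, and a synthetic-data generator
    with planted modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    SummarizedExperiment,
    S4Vectors,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'comberon-package.R'
    'dendrogram.R'
    'distances.R'
    'io.R'
    'measures.R'
    'methods.R'
    'pairs.R'
    'peaks.R'
    'pipeline.R'
    'plots.R'
    'stats.R'
    'synthetic.R'
    'utils.R'
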