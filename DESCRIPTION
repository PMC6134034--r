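Package: dmrnet
Title: Differentially Methylated Region Co-Methylation Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery of differentially methylated region (DMR) networks from
    Illumina-style beta-value methylation matrices. Implements probe-level
    exclusion filtering, a lasso-radius DMR caller with Stouffer-combined
    region significance, weighted co-methylation networks over DMR CpGs
    (soft-thresholded absolute-correlation adjacency, scale-free fit based
    soft-threshold selection, topological overlap measures, module
    detection), aggregation of topological overlap to DMR pairs, thresholded
    DMR-network extraction with cross-cohort replication, Fisher-z
    meta-analysis of methylation-trait correlations, and a synthetic
    multi-cohort data generator with planted DMR networks for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
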