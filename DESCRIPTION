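Package: CNAsubtypes
Title: Copy-Number Aberration Analysis and Genomic Subtyping of Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for somatic copy-number analysis of
    array-CGH tumor cohorts: circular binary segmentation of per-probe log2
    ratios, sample-adaptive gain/loss calling with fraction-of-genome-altered
    summaries, permutation-based scoring of recurrent aberrations with FDR
    control and peak peel-off, recurrent high-level amplicon cataloguing with
    coamplification statistics, copy-number/expression dosage-correlation
    analysis, hierarchical genomic subtyping with expression centroid export
    and nearest-centroid classification, and survival comparison across
    subtypes. Includes a synthetic-cohort generator emulating breast-cancer
    subtype archetypes so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    survival,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'amplicons.R'
    'cohort-io.R'
    'expression-integration.R'
    'gistic.R'
    'pipeline.R'
    'segmentation.R'
    'subtyping.R'
    'survival-analysis.R'
    'synthetic-cohort.R'
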