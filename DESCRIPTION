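Package: snregnet
Title: Cell-Subtype-Specific Cis-Trans Regulatory Prioritization from
    Parallel Single-Nucleus RNA and ATAC Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis workflow for parallel single-nucleus
    RNA-seq and ATAC-seq case-control studies. Provides per-nucleus quality
    control and hybrid-score multiplet removal, cross-modality cluster
    linking with Jaccard validation, donor-level cohort statistics and
    bootstrapped cell-proportion tests, iterative principal-component
    covariate selection, two-part hurdle differential expression with donor
    random effects, binomial likelihood-ratio differential accessibility,
    dynamic-lambda Poisson peak calling with Fisher-method consensus,
    cis-co-accessibility networks from distance-penalized sparse inverse
    covariance estimation with Louvain community extraction, candidate
    cis-regulatory element to target-gene linking, exact-threshold motif
    scanning and GC-matched enrichment, importance-sampling tests of SNP
    effects on transcription-factor binding affinity, and cross-study
    consensus calling for differential genes and peaks. A synthetic-data
    generator with a machine-readable truth ledger supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    MASS,
    lme4,
    igraph,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
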