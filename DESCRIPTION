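Package: lnclink
Title: Multi-Tissue lncRNA Endurance-Training Response Analysis with
    Chromatin Accessibility Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing long non-coding RNA (lncRNA) responses
    to endurance exercise training in multi-tissue, two-sex, multi-timepoint
    designs. Provides expression filtering and timewise sex-stratified
    differential calling (CPM/FPKM/TMM/median-of-ratios normalization),
    Fisher sum-of-logs sex meta-analysis with covariate-weighted FDR,
    Z-score trajectory summaries and sex-specificity classification,
    fuzzy c-means temporal clustering, sequence and structural feature
    characterization (ORF scanning, base-pairing folding proxy), and the
    integration of lncRNAs with local ATAC-seq chromatin accessibility via
    distance-window pairing, trajectory correlation, and activity-score
    prioritization of lncRNA-peak-gene triads. A negative-binomial
    synthetic-data generator emulates the full study design so the entire
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    Rcpp,
    S4Vectors,
    data.table,
    fgsea,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    e1071,
    edgeR,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
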