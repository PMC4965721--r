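Package: conmeth
Title: Consistent Differentially Methylated Region Discovery in
    Case-Control Bisulfite Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tile-based discovery and characterization of consistent
    differentially methylated regions (C-DMRs) from per-CpG bisulfite
    read counts in case/control cohorts. Aggregates CpG calls onto fixed
    1000 bp tiles with coverage filters, calls per-sample-pair DMRs with
    Fisher's exact test and Benjamini-Hochberg FDR, tests cross-sample
    consistency with a binomial model validated by sample- and
    region-permutation tests, computes per-region Shannon methylation
    entropy, annotates regions with genic context (promoter, UTRs, exons,
    introns, CpG islands, shores, repeats, enhancers), relates methylation
    to expression by quartile metagene profiles and per-class
    correlations, and compares correlation-network modules between
    differential methylation and expression matrices (cross-tabulation,
    eigengene correlation, permutation preservation Z). Includes a
    synthetic cohort generator with planted region classes and a
    machine-readable truth table so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
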