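Package: flankcapture
Type: Package
Title: Restriction-Flank Methylation Capture: Design, Simulation, and
    Cell-Type Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating restriction-enzyme anchored
    methylation sequencing assays that capture the flanks of CCGG (MspI) or
    TCGA (TaqI) motifs. Provides in silico digestion and flank/RRBS region
    construction with theoretical coverage statistics, a fragment-capture and
    read simulator with an enzymatic-conversion error model, fragment-level
    methylation (PAT) input/output and titration mixing, genome segmentation
    and one-vs-all cell-type marker discovery, fragment-level (UXM-style) and
    CpG-level non-negative least squares deconvolution of cell-type mixtures,
    and a z-score cell-of-origin classifier with ROC/AUC evaluation. A
    synthetic-data module generates genomes, cell-type methylomes with planted
    markers, and titration cohorts with known truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rcpp,
    pracma,
    stringi,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
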