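Package: mirlocus
Title: miRNA Differential Expression, Imprinted-Locus Co-Localization and
    Target-Pathway Recurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for two-group small-RNA sequencing studies:
    negative-binomial differential expression of miRNAs with
    Benjamini-Hochberg correction, quantification of DE-miRNA
    co-localization within a named genomic locus (hypergeometric and
    permutation nulls), seed-match target prediction over 3'UTRs with
    alignment-score and duplex-energy filters, per-miRNA pathway
    enrichment with a cross-miRNA recurrence statistic, read-level
    small-RNA QC summaries, and 2^-ddCt qPCR validation analysis. A
    synthetic-data module generates every input with planted ground truth
    so the full chain is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
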