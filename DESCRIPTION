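Package: enhancerAE
Title: Aberrant Enhancer Discovery and Prognostic Scoring from Paired
    Tumor/Normal Epigenome-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative pipeline for identifying aberrant enhancers in
    paired tumor/normal designs: builds a merged enhancer catalog from
    per-sample histone-mark peaks and chromatin-state calls, calls
    differentially expressed enhancers (eRNA), genes, and differentially
    methylated loci/regions with paired tests, links intergenic
    differentially expressed enhancers and genic differentially methylated
    enhancers to target genes by distance-constrained Spearman correlation,
    scores cross-cohort concurrence and platform-aware replication rates,
    confirms enhancer-gene pairs against TAD/loop topology, and applies a
    six-gene aberrant-enhancer prognostic risk score with a
    log-rank-minimizing cutoff. Ships a synthetic-data generator with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
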