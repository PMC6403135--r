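Package: methylrhythm
Title: Daily Whole-Genome Bisulfite Methylome Analysis with Circadian
    Transcriptome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for daily (diel/circadian) DNA methylome
    dynamics from whole-genome bisulfite sequencing in plants. Reads
    per-cytosine count reports, estimates context-specific (CG/CHG/CHH)
    methylation levels with lambda spike-in non-conversion correction,
    calls differentially methylated cytosines (Fisher exact test with
    Benjamini-Hochberg correction) and regions (DMC clustering), assigns
    calls to genes, promoters and transposable-element families, computes
    metagene profiles, detects 24 h rhythmic genes by harmonic regression,
    and correlates region-level methylation with gene expression. Includes
    a synthetic-data generator with a planted-truth ledger so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
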