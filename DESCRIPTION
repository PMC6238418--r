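Package: promarch
Title: Promoter Architecture Analysis from Nascent Transcription and Chromatin Accessibility Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strand-resolved processing of NET-seq nascent-transcription tags
    (PCR-duplicate and splicing-intermediate removal), MNase-seq and ATAC-seq
    fragment-length partitioning, 1x depth normalisation, TSS-anchored
    metaprofiles, and promoter-level statistics for two-condition knockdown
    studies: travelling ratio of RNA polymerase II, divergent antisense
    transcription in the 1-kb window upstream of the TSS, expression quantile
    classes, differential-expression gene classification, and
    slope-comparison z statistics. Includes a fully seeded multi-assay
    synthetic data generator with ground-truth labels so every planted effect
    (pause peaks, antisense gain, upstream nucleosome loss, expression fold
    changes) is recoverable and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
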