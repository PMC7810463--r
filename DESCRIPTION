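Package: bifate
Title: Integrative Transcriptome and Chromatin Accessibility Analysis of
    Bi-Fated Attachment Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a transitional cell population (such as the
    tendon-to-bone attachment cells of the enthesis) is "bi-fated", i.e.
    expresses a mixture of the transcriptional programs of its two neighbouring
    cell types while borrowing their open-chromatin landscapes. The package
    implements a mixed-transcriptome gene classifier for five-compartment bulk
    RNA-seq designs, a replicate-voting ATAC-seq consensus peak pipeline
    (merge, extend to a minimum length, normalize, vote, filter), a three-way
    accessibility-sharing classifier with promoter/distal annotation and 2x2
    contingency statistics (with optional Yates correction), an evidence-based
    shared-enhancer prioritizer, and KLF/CACCC-box motif scanning and gene-set
    enrichment. A seeded synthetic-data generator with known ground truth makes
    every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
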