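Package: rdcnv
Title: Read-Depth CNV Calling, Region Merging, Annotation and Population
    Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from per-window normalized
    read depth in multi-individual whole-genome resequencing panels, merges
    correlated adjacent windows into calls and calls into copy number
    variation regions (CNVRs), accounts for shared and population-specific
    CNVRs across populations, annotates regions by genic context, gene
    overlap, term enrichment and QTL intersection, scans population pairs
    with the Vst differentiation statistic, and validates copy number by
    qPCR 2^-ddCt estimates.  A synthetic-data module simulates
    multi-population depth matrices with planted CNVs so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
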