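Package: secircuit
Title: Lineage-Selective Super-Enhancer Calling and Core Regulatory
    Circuitry Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering lineage-selective super enhancers from
    H3K27ac ChIP-seq peak and signal data across differentiating cell
    types, linking enhancers to target genes with an activity-by-contact
    score, assembling core regulatory circuitries of super-enhancer
    regulated transcription factors via exact-p-value motif scanning, and
    scoring GWAS variants inside enhancer functional regions for
    allele-specific transcription-factor binding changes.  Includes a
    deterministic synthetic-data generator with planted ground truth so
    the whole pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
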