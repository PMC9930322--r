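Package: cobindseq
Title: Multi-Factor ChIP-Seq Co-Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of transcription-factor co-occupancy from multi-factor
    ChIP-seq experiments. Provides a simplified fold/Poisson/FDR peak caller
    with input control, fixed-width peak resizing, gap-tolerant multi-factor
    region collapsing, a random-overlap Poisson positivity statistic that
    classifies each collapsed region as positive or negative per factor,
    co-binding signature tabulation at region and gene level (TSS-window
    assignment), genomic-context annotation, promoter histone-mark signal
    quantification with global-TSS normalization, known-motif PWM scanning
    with co-occurrence enrichment, integration with differential-expression
    calls, hypergeometric gene-set over-representation, and a fully seeded
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
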