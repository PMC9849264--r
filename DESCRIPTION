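Package: perinet
Title: Perinatal Cardiomyocyte Regulatory Network from Accessibility,
    HiChIP Contacts and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs a perinatal cardiomyocyte regulatory network by
    integrating chromatin accessibility count matrices, H3K27ac HiChIP
    contact maps and gene expression. Provides TMM normalization with an
    exact conditional negative-binomial test for differential
    accessibility and expression, distance-decay binomial loop calling on
    binned contact maps with ICE balancing, differential looping,
    aggregate peak analysis (P2LL) and virtual 4C, loop-based
    enhancer-to-gene assignment with a randomized-pair correlation null,
    PWM motif scanning and enrichment, and transcription-factor
    regulatome construction. A synthetic multi-omics study generator with
    full ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    mclust
Config/testthat/edition: 3
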