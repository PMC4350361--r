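Package: lncmyc
Title: MYC Regulation of the Long Non-Coding Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for studying transcription-factor control of the
    long non-coding transcriptome in a MYC-inducible cell system. Provides
    counts-per-million normalization and row-centered log2 fold-change
    matrices, a negative-binomial exact test for differential expression with
    fold-change and p-value thresholding, strand-aware ChIP-seq peak-to-TSS
    occupancy assignment, detection and functional classification of
    bidirectional (divergent) promoters, a linear-discriminant classifier for
    polyadenylation status from paired poly-A-selected and ribosome-depleted
    libraries, transcript half-life estimation from transcription-shutoff
    time courses, delta-delta-Cq qPCR and nuclear run-on quantification, and
    a synthetic-data generator with planted ground truth so every stage is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
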