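Package: promvar
Title: Promoter Expression Variability and TSS Architecture from CAGE Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies promoter expression variability across individuals
    from CAGE 5'-end data. Builds CAGE-inferred promoters by positional tag
    clustering of CTSSs, computes expression-adjusted dispersion (log10 CV2
    corrected by a running median over mean expression), decomposes
    multi-modal promoters into core promoters by local-maxima decomposition,
    derives TSS architecture metrics (width-normalized Shannon entropy,
    IQR width, decomposed-promoter correlation, CAGE/MNase positional
    cross-correlation), and maps cis QTLs for promoter expression,
    decomposed-promoter expression and decomposed-promoter usage fractions,
    including detection of expression-stabilizing TSS switches. A synthetic
    CAGE panel generator with planted ground truth supports end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
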