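Package: mztscreen
Title: Screening Sexed Pre-Blastoderm Embryo Transcriptomes for Zygotic
    and Male-Limited Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for early-embryo transcript screening in
    sexed RNA-seq libraries: Phred-quality read trimming (modified Mott
    maximum-scoring-segment algorithm) and ambiguity/length filtering,
    RPKM quantification with per-comparison quantile normalisation, a
    weighted proportions (Baggerly-style) differential-expression test
    with between-library overdispersion and Benjamini-Hochberg FDR
    control, marker-calibrated expression-threshold filters, principal
    coordinates sample QC, and the multi-comparison set-intersection
    screen that separates maternally deposited from zygotically
    activated and male-upregulated transcripts. Includes a
    negative-binomial synthetic-data generator with ground-truth
    transcript classes emulating the eight-library two-sex, two-stage
    embryo design, so every stage is testable without raw sequence
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
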