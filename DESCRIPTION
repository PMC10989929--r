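Package: chaseterm
Title: Transcript Decay Kinetics and Premature Termination from
    Rifampicin-Chase RT-qPCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers RNA decay constants, half-lives, relative synthesis
    rates and premature transcription-termination fractions from
    rifampicin-chase RT-qPCR time courses and steady-state transcript
    intensities, under a single-promoter steady-state model in which
    transcript level equals synthesis rate over decay constant. Provides
    delta-delta-Ct relative quantification, pooled nonlinear
    least-squares exponential decay fitting with series-level bootstrap
    confidence intervals, the synthesis-ratio / termination calculus for
    comparing 5' UTR and coding-region segments across conditions, an
    RNase E cleavage-site scanner (+2U and -3/4A rules), U-tract
    detection, clustering of mapped RNA 3'-end positions, and a seeded
    generator of synthetic chase experiments for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
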