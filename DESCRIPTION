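Package: sedqual
Title: Sediment Quality Indices for Heavy-Metal Contamination Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes composite sediment quality indices for heavy-metal
    contamination of benthic sediments, centred on the modified hazard
    quotient (mHQ), a per-metal severity index built from the threshold,
    probable and severe effect levels (TEL, PEL, SEL), and the ecological
    contamination index (ECI), a site-level aggregate weighted by the
    reciprocal of the leading eigenvalue of a correlation-matrix principal
    component analysis of the metal concentrations. Also provides the
    classical comparison suite (contamination factor, degree-of-contamination
    shares, pollution load index, Hakanson potential ecological risk,
    risk assessment code and individual contamination factor from Tessier
    five-fraction speciation data, effect-level hazard quotients),
    correlation PCA with varimax rotation, bundled case-study data and
    guideline constants, a seeded synthetic fraction-data generator, and an
    end-to-end pipeline with rank-concordance reporting and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
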