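Package: rabclass
Title: Identification and Subfamily Classification of Rab GTPases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-phase pipeline that decides whether a protein sequence is a
    Rab GTPase and, if so, assigns it to a Rab subfamily with a calibrated
    confidence score. Phase one filters candidates through a pooled G-domain
    profile, a best-hit search against a curated reference set of Rab and
    non-Rab GTPases, and a scan for the five diagnostic RabF sequence motifs
    with exact position p-values. Phase two scores the candidate against
    per-subfamily position-specific scoring matrices and pairwise best hits,
    applying a 40 percent identity gate and an undetermined-subfamily (RabX)
    fallback. Includes Markov clustering of RabX sequences into hypothetical
    subfamilies, ROC-based calibration of the confidence cutoff, a seeded
    synthetic benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
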