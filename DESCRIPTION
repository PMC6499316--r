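Package: editscan
Title: Quantification of Genome-Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for estimating CRISPR genome-editing
    outcomes from amplicon deep-sequencing reads: quality filtering,
    primer-based read assignment, global read-to-amplicon alignment with
    an indel-event-penalizing scoring scheme and free end gaps, extraction
    and left-normalization of edit events, primer-dimer and off-target
    artifact filtering, event-level normalization against matched
    controls, and quantification of editing efficiency, frameshift
    fraction, read heterogeneity, and HDR/base-editing rates. Includes a
    seeded synthetic-read simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
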