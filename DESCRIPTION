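Package: spacertrace
Title: Spacer Acquisition Analysis for CRISPR Reporter Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Spacertrace", "Developers", email = "spacertrace@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing naive CRISPR-Cas adaptation from long-read
    amplicon sequencing of an expanded reporter array. Extracts newly
    acquired spacers from noisy reads by error-tolerant repeat matching,
    maps protospacers to chromosome and plasmid references with strand and
    PAM annotation, computes hotspot bin maps, plasmid-versus-chromosome
    source bias with molar-excess normalisation, PAM position-frequency
    matrices, and reading-frame start/stop-codon enrichment statistics.
    Ships a seeded synthetic-data generator emulating nanopore amplicon
    pools with planted acquisition events, and a command-line pipeline that
    runs simulate, extract, map and analyse stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
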