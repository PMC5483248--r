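Package: crescan
Title: Cross-Species Binding-Site Discovery with Position-Specific
    Scoring Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds information-content scoring matrices (bits) from
    collections of aligned transcription-factor binding sites, calibrates
    a detection threshold by receiver operating characteristic (ROC)
    analysis on a genome with known sites, scans target genomes for
    candidate sites, and characterizes candidates by score, genomic
    context and dyad (palindrome) symmetry.  Designed for cross-species
    motif transfer in bacteria, e.g. using catabolite-responsive element
    (cre) sites bound by CcpA to find operators of related LacI-family
    regulators.  Includes a seeded synthetic-data generator (site
    collections drawn from a frequency matrix, background genomes,
    planted-site benchmarks) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
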