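Package: remotethread
Title: Remotely Conserved Protein Domain Detection by Relaxed Profile
    Search and Fold-Recognition Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects remotely conserved protein domains by combining
    relaxed profile-based domain searches (E-value ceiling 50) with a
    fold-recognition confirmation step. Weak profile hits are threaded
    against a structure library and the resulting Z-score ranking is
    scored with a combined statistic, the empirical-CDF tail probability
    of the best expected structure's Z-score multiplied by a
    hypergeometric over-representation p-value of the expected structures
    in the top window of the ranking. Includes cross-species ortholog
    validation, essential-residue classification under BLOSUM62, a
    hide-and-seek benchmark framework over paired profile-database
    releases with clan-aware confusion metrics, and deterministic
    synthetic fixture generators so the whole system is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
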