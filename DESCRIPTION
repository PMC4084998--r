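Package: fpscan
Title: First-Passage Statistics of Amino-Acid Sequences Across Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-passage analysis of protein primary sequences.
    Counts, for every ordered amino-acid pair, the distance from each
    occurrence of one amino acid to the first subsequent occurrence of
    another within a protein chain; fits the exponential background of the
    resulting first-passage distributions; scores and calls significant
    deviations (peaks) from that background; compares fitted decay constants
    with the geometric law implied by independent residues; and aggregates
    peak amplitudes across organisms to quantify their dependence on optimal
    growth temperature. Includes a synthetic proteome generator with
    controllable composition, temperature trends and planted lag
    correlations, so the whole pipeline is testable without external data.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
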