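Package: toxsel
Title: Fluctuation Analysis and Stringency Metrics for Toxin-Based
    Negative Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for characterising inducible-toxin
    negative-selection (counterselection) cassettes in enteric bacteria.
    Implements the p0 (null-class) Luria-Delbruck fluctuation-test
    estimator of mutation rates with exact confidence intervals,
    colony-forming-unit quantification from serial-dilution plate counts,
    selection-stringency frequencies with detection-limit handling and
    log-space replicate aggregation, theoretical cassette-mutability
    bounds derived from genomic mutation-rate intervals, and
    coverage-based presence/absence screening of candidate toxin genes
    from tabular alignment hits. A stochastic simulator generates every
    input kind (fluctuation well outcomes under a birth-and-mutation
    process, Poisson dilution plating, rare-escape assays, alignment hit
    tables) so all analyses are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    yaml,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
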