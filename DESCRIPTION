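Package: nnnfit
Title: Next-Nearest-Neighbor Analysis of Antisense Inhibition Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits next-nearest-neighbor (NNN) triplet models to antisense
    oligonucleotide inhibition experiments by error-weighted, rank-deficient
    least squares via singular value decomposition, with explicit handling of
    the circular-sequence constraint algebra that governs which parameter
    combinations are identifiable. Provides circular overlapping k-mer
    counting, design-matrix construction with cell-line and gene covariates,
    chi-square goodness-of-fit testing, scoring and window scanning of mRNA
    target sequences with propagated uncertainties, linear-independence and
    estimability diagnostics, and a synthetic-data generator for calibration
    studies. Ships a published table of fitted triplet inhibition parameters
    for immediate target scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
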