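Package: bitbowr
Title: Design and Analysis of Combinatorial Fluorophore (Bitbow) Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative machinery for Bitbow-style combinatorial fluorescent
    barcoding experiments, in which each fluorophore module recombines
    independently to an ON or OFF state so that N modules yield 2^N - 1
    nonzero binary color codes. Provides code capacity and Shannon-entropy
    diagnostics, construction of code probability distributions from
    per-module recombination frequencies, birthday-problem collision-rate
    estimation (closed form, analytic, and Monte Carlo), low-frequency code
    whitelisting, coupon-collector simulation of the number of animals needed
    to sample every lineage, a multichannel color-calling pipeline (linear
    spectral unmixing, path smoothing, sum-normalization, per-channel bit
    calling, soma/neurite consistency statistics), and a synthetic-data
    module that generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    pracma,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
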