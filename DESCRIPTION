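Package: proformr
Title: Post-Identification Analysis of Top-Down Proteomics Proteoform Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for the post-identification stages of label-free
    quantitative top-down proteomics: target-decoy false discovery rate
    filtering of proteoform-spectrum matches, cross-run retention-time
    alignment by locally weighted regression, median-ppm mass recalibration,
    hierarchical mass/retention-time clustering with match-between-runs
    identification transfer, intensity roll-up across ion-mobility
    compensation-voltage channels, two-way median-polish normalization,
    empirical-Bayes moderated paired t-tests, hypergeometric presence/absence
    tests, delta-mass modification annotation, and prohormone processing-region
    annotation. Includes a synthetic-data generator emulating a paired
    multi-donor islet study design so every stage is testable without raw
    mass-spectrometry data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
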