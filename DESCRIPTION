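Package: umiecs
Title: Error-Corrected Sequencing with Unique Molecular Indexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Targeted error-corrected sequencing (ECS) for ultra-rare variant
    quantification. Reads carrying random molecular indexes are grouped into
    read families, per-family error-corrected consensus sequences (ECCS) are
    built by within-family comparison, and variant allele fractions are
    computed from the number of read families supporting the variant versus
    the reference allele at each queried locus. Includes residual error
    profiling at wild-type sites (per-substitution-class specificity
    thresholds, raw versus corrected VAF distributions) and a molecule-level
    simulator of indexed amplicon libraries with PCR, sequencing and
    oxidative-damage error processes, used to reproduce a spike-in dilution
    benchmark with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
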