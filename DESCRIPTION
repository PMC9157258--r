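Package: cysredox
Title: Quantitative Cysteine Redox Proteomics from iodoTMT Reporter Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative redox proteomics with sequential iodoTMT
    labelling. Reads MaxQuant-style modification-specific peptide tables,
    filters decoy/contaminant/non-cysteine records, normalizes reporter
    channels by median-of-medians within condition and thiol state, computes
    per-replicate percent oxidation of cysteine thiols as 100*Sox/(SH+Sox),
    tests differential oxidation between two conditions with a pooled-variance
    t-test and permutation-based FDR, calls condition-specific oxidation,
    bins peptides into oxidation classes, maps peptide cysteines to protein
    coordinates and matches disulphide annotations. Includes a synthetic-data
    generator (in-silico trypsin/P digestion, ground-truth oxidation fractions,
    lognormal reporter noise, intensity-dependent missingness) so the whole
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
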