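Package: gdrepertoire
Title: Gamma-Delta T Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bulk-sequenced gamma-delta T cell receptor (TRG/TRD)
    repertoires from clonotype tables. Provides readers and writers for AIRR
    Rearrangement TSV and a legacy 11-column clonotype dialect, library-level
    quality control with error-correction merging of low-abundance clonotypes,
    segment usage and CDR3 spectratype summaries, junctional-insert and
    convergence statistics, diversity and clonality estimation (Chao1,
    Efron-Thisted, D50, Shannon, inverse Simpson, frequency compartments),
    cross-sample overlap and public-clonotype classification, nonparametric
    association of repertoire features with clinical covariates, and a
    seeded synthetic cohort generator that emulates blood and skin TRG/TRD
    repertoire structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
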