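Package: probioprofile
Title: In Vitro Probiotic Profiling of Lactic Acid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for characterising candidate probiotic lactic acid
    bacteria. Provides a heuristic surface-proteome classifier (signal
    peptide, lipobox, and LPXTG sortase-anchor detection) with Kyte-Doolittle
    GRAVY hydropathy profiling and group statistics (Welch t, Mann-Whitney U);
    calculators for crystal-violet biofilm classification, autoaggregation,
    coaggregation, and bacterial-adhesion-to-solvents (BATS) assays; a
    principal-component analysis of stress-retention profiles for ranking
    isolates; and seeded synthetic-data generators (proteomes with planted
    surface motifs, assay plates, stress panels) so every stage is testable
    without external downloads.
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
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
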