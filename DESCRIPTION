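Package: sbpmir
Title: Microsynteny, Duplication Dating and miR156 Origin Analysis for
    SBP-Box Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for studying the expansion of the
    plant SBP-box (SPL) transcription-factor family and its regulator
    miR156. Implements micro-fragment synteny detection (61-gene windows,
    >= 10 homologous gene pairs), tandem versus segmental duplication
    classification, NG86 Ka/Ks estimation with codon back-threading and
    one-to-many Ks aggregation, WGD-era Ks binning, homology-based miR156
    locus prediction with base-pair-maximisation hairpin evaluation,
    miRNA-target complementarity scoring, miR156-SBP co-location and
    face-to-face origin detection, and group-level functional profiling.
    Ships a synthetic-genome generator that plants tandem and segmental
    duplications, diverged coding sequences at target Ks, miR156 loci and
    convergent gene pairs with a machine-readable truth ledger, so every
    pipeline stage is testable without genome downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
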