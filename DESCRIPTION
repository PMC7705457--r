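Package: mtdigenic
Title: Digenic Modifier Analysis for Homoplasmic Mitochondrial DNA Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying digenic inheritance of homoplasmic
    mitochondrial DNA variants with heterozygous nuclear modifier alleles,
    motivated by reversible infantile respiratory chain deficiency (RIRCD).
    Implements damaging-variant classification and rarity filtering,
    pedigree-stratified segregation partitioning, cumulative damaging-allele
    burden comparison across affected carriers, unaffected carriers and
    population controls, carrier-frequency and digenic co-occurrence
    arithmetic with penetrance and prevalence prediction, glutamate/glutamine
    residue-composition analysis of mitochondrially encoded proteins against
    expression change, qPCR delta-Ct mitochondrial DNA copy-number
    quantification, proteome log2-ratio regulation thresholds, and seeded
    simulators that generate cohorts, genotypes, expression and assay tables
    with the statistical structure the analysis assumes.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
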