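Package: exrepeat
Title: Repeat Expansion Genotyping, Triage and Cohort Metrics for Exome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening exome-sequencing cohorts for short tandem repeat
    (STR) expansions at catalogued repeat expansion disease loci. Provides a locus
    catalogue with unit and base-pair pathogenicity cutoffs, a seeded synthetic
    cohort generator emulating exome capture-kit target maps and read-length-limited
    read evidence, a simplified evidence-based repeat genotyper producing
    ExpansionHunter-style calls with exact and lower-bound alleles, a deterministic
    pass/borderline/fail triage rule engine with repeat-interruption screening, and
    cohort-level summaries of genotyping rate and locus coverage stratified by
    capture kit and read length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
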