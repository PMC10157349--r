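Package: ecgermline
Title: Germline Multigene Panel Burden Analysis for Endometrial Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of germline pathogenic variants in
    endometrial cancer: a six-rule variant prioritization cascade with
    ClinVar-based rescue, a simplified pathogenicity classifier, an encoding of
    national Lynch-syndrome and hereditary breast/ovarian cancer germline
    testing indication criteria, gene-level carrier burden estimation (odds
    ratios with Woolf confidence intervals, chi-square/Fisher tests),
    clinicopathological subgroup summaries, and a seeded synthetic cohort
    generator that emulates the statistical structure of a 527-case/1,662-control
    study so the whole pipeline is testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
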