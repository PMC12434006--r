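Package: faersdispro
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for pharmacovigilance signal detection in
    FDA Adverse Event Reporting System (FAERS) quarterly ASCII data:
    parsing and writing the dollar-delimited dialect, case-version
    deduplication and deleted-report removal, cohort construction by
    primary-suspect drug for immune-checkpoint-inhibitor mono- and
    combination therapy, baseline description with Cramer's V,
    reporting odds ratio (ROR) and Bayesian information-component (BCPNN)
    disproportionality statistics with a joint dual-criteria signal rule,
    Benjamini-Hochberg false-discovery-rate control, preferred-term to
    system-organ-class aggregation, and a fully parameterised synthetic
    spontaneous-reporting generator with planted signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
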