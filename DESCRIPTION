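Package: rorscreen
Title: Case/Non-Case Disproportionality Screening for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from individual
    case safety report (ICSR) line listings using the case/non-case
    design. Selects cases by adverse-event term, builds per-drug-class
    two-by-two contingency tables at the report level, computes the
    reporting odds ratio (ROR) with Woolf (log-normal) confidence
    intervals and Pearson chi-square p-values, applies a minimum
    exposed-case filter, and summarises the case series (demographics,
    time to onset, seriousness, outcomes, countries, drug-mention
    shares). A synthetic spontaneous-reporting database generator with
    configurable exposure prevalences and injected reporting-rate ratios
    supports end-to-end testing and operating-characteristic evaluation
    (type-I error, power) without access to a proprietary
    pharmacovigilance database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
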