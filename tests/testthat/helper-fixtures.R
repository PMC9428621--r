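# Shared miniature fixtures, built in code.

TARGET <- "LLT_ANMDARE"

toy_class_map <- function() {
  class_map(
    tibble::tibble(
      pattern = c("gardasil", "cervarix", "hpv vaccine",
                  "influenza vaccine", "dtp"),
      class_id = c("HPV", "HPV", "HPV", "INFLUENZA", "DTP_POLIO"),
      match = c("exact", "exact", "exact", "prefix", "prefix")
    ),
    labels = tibble::tibble(
      class_id = c("HPV", "INFLUENZA", "DTP_POLIO"),
      label = c("HPV vaccine", "Influenza vaccine", "DTP-polio vaccine")
    )
  )
}

# four reports spanning the 2x2: case+exposed, case-unexposed,
# non-case+exposed, non-case-unexposed
toy_reports <- function() {
  icsr_reports(
    report_id = c("r1", "r2", "r3", "r4"),
    age_years = c(13, 25, NA, 48),
    sex = c("female", "male", "unknown", "female"),
    country = c("FR", "JP", NA, "GB"),
    drugs = c(
      paste0("Gardasil|suspect||2021-01-01"),
      paste0("aspirin|suspect||2021-01-01"),
      paste0("Gardasil|suspect||2021-03-01"),
      paste0("aspirin|suspect||2021-03-01")
    ),
    events = c(
      paste0(TARGET, "|Anti-NMDA receptor encephalitis|2021-01-05"),
      paste0(TARGET, "|Anti-NMDA receptor encephalitis|2021-01-10"),
      "LLT_OTHER|Headache|2021-03-02",
      "LLT_OTHER|Headache|2021-03-04"
    ),
    seriousness = c("hospitalization", "disabling", "", ""),
    outcome = c("recovered", "not_recovered_or_sequelae", "unknown",
                "unknown")
  )
}

# the published screen as a virtual contingency table
published_ctab <- function() {
  counts <- anmdare_vaccine_counts()
  contingency_from_counts(counts, attr(counts, "n_cases"),
                          attr(counts, "n_reports"), term_code = TARGET)
}
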