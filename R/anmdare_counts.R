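#' Published screening counts: anti-NMDAR encephalitis and vaccines
#'
#' Per-vaccine-class exposure counts for the worked example: reports of
#' anti-NMDA receptor encephalitis in a worldwide spontaneous-reporting
#' database up to end 2021 (70 case reports among 29,758,737 reports in
#' total). `a` is the number of case reports with the class as a suspect
#' drug; `b` the number of non-case reports with the class.
#'
#' Only the eight classes at or above the minimum of three exposed cases
#' have published cell counts. The five classes below the filter (rabies,
#' typhoid, hepatitis A/B combinations and components) were reported only
#' as present with fewer than three case reports each; their `a` values
#' here are a synthetic completion consistent with the published totals
#' (51 suspect vaccine mentions over the case series, each class below
#' 3) and their `b` values are synthetic placeholders. These rows fall
#' out of the statistical screen by construction and carry no published
#' statistics; the `synthetic_b_below_filter` attribute names them.
#'
#' @return Tibble with columns `class_id`, `label`, `a`, `b` and
#'   attributes `n_cases` (70) and `n_reports` (29,758,737).
#' @export
#' @examples
#' counts <- anmdare_vaccine_counts()
#' ctab <- contingency_from_counts(counts, attr(counts, "n_cases"),
#'                                 attr(counts, "n_reports"))
#' screen_counts(ctab)
anmdare_vaccine_counts <- function() {
  out <- tibble::tibble(
    class_id = c("HPV", "DTP_POLIO", "INFLUENZA", "VARICELLA",
                 "PNEUMOCOCCAL", "HIB", "COVID19", "YELLOW_FEVER",
                 "RABIES", "TYPHOID", "HEP_AB", "HEP_A", "HEP_B"),
    label = c("HPV vaccine", "DTP-polio vaccine", "Influenza vaccine",
              "Varicella zoster vaccine", "Pneumococcal vaccine",
              "HIB vaccine", "COVID-19 vaccine", "Yellow fever vaccine",
              "Rabies vaccine", "Typhoid vaccine",
              "Hepatitis A/B vaccine", "Hepatitis A vaccine",
              "Hepatitis B vaccine"),
    a = c(8L, 8L, 7L, 5L, 4L, 4L, 4L, 3L, 2L, 2L, 2L, 1L, 1L),
    b = c(116283L, 70006L, 280525L, 193141L, 241627L, 89544L,
          2881218L, 26614L, 6474L, 1755L, 12076L, 8039L, 63735L)
  )
  attr(out, "n_cases") <- 70L
  attr(out, "n_reports") <- 29758737L
  attr(out, "synthetic_b_below_filter") <- c("RABIES", "TYPHOID", "HEP_AB",
                                             "HEP_A", "HEP_B")
  out
}
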