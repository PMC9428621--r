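#' Time to onset after exposure
#'
#' Days from the latest administration of a suspect drug of the given
#' class on or before event onset to the earliest onset of a matching
#' event term. Absent if either date is missing; pairs where every
#' administration post-dates onset are rejected as absent with a
#' warning (implausible chronology rather than a negative lag).
#'
#' @param reports An ICSR tibble.
#' @param class_id Drug class whose administration anchors the interval.
#' @param term A [term_selector()] or term code.
#' @param cm A [class_map()].
#' @param fmt An [icsr_format()].
#' @return Numeric vector of whole days (`NA` where not computable), one
#'   per report row.
#' @export
time_to_onset <- function(reports, class_id, term, cm,
                          fmt = icsr_format()) {
  term <- as_term_selector(term)
  if (!nrow(reports)) return(numeric(0))
  ev <- icsr_events(reports, fmt)
  hit <- if (!is.null(term$code)) {
    ev$term_code == term$code
  } else {
    tolower(ev$term_name) == tolower(term$name)
  }
  ev <- ev[hit & !is.na(ev$onset_date), , drop = FALSE]
  if (!nrow(ev)) return(rep(NA_real_, nrow(reports)))
  onset <- ev |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(onset = min(.data$onset_date), .groups = "drop")

  dl <- icsr_drugs(reports, fmt)
  dl <- dl[dl$role == "suspect" & !is.na(dl$administration_date), ,
           drop = FALSE]
  dl$class_id <- map_drug_class(dl$drug_name, cm, class_id = dl$class_id)
  dl <- dl[dl$class_id == class_id, , drop = FALSE]
  if (!nrow(dl)) return(rep(NA_real_, nrow(reports)))

  both <- dplyr::inner_join(dl, onset, by = "report_id")
  both <- both |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      onset = .data$onset[1],
      admin = if (any(.data$administration_date <= .data$onset[1])) {
        max(.data$administration_date[
          .data$administration_date <= .data$onset[1]])
      } else as.Date(NA),
      any_admin = dplyr::n() > 0,
      .groups = "drop"
    )
  rejected <- both$report_id[both$any_admin & is.na(both$admin)]
  if (length(rejected)) {
    warn(paste0("administration after onset for report(s) ",
                paste(head(rejected, 5), collapse = ", "),
                "; time to onset set to missing"))
  }
  tto <- as.numeric(both$onset - both$admin)
  out <- rep(NA_real_, nrow(reports))
  out[match(both$report_id, reports$report_id)] <- tto
  out
}

#' Descriptive summary of a case series
#'
#' Computes the standard descriptive profile of a pharmacovigilance case
#' series: vaccine involvement, sex and age distribution (age strata
#' \[0, 15) and \[15, 30\], boundary assigned upward), time to onset
#' across exposed classes (per case, the shortest administration-to-onset
#' interval), seriousness and outcome breakdowns, reporting-country
#' shares, and suspect drug-class mention shares. Every percentage is
#' computed over, and reported with, its known-value denominator;
#' medians use the even-`n` midpoint convention. Drug-class shares are
#' mention-level (each suspect drug entry that resolves to a class
#' counts once), unlike the report-level contingency counting.
#'
#' @param cases An ICSR tibble of case reports only.
#' @param n_reports Total number of reports in the database the cases
#'   came from (for context in the output).
#' @param cm A [class_map()].
#' @param term A [term_selector()] or term code.
#' @param fmt An [icsr_format()].
#' @return An object of class `case_summary`.
#' @export
summarize_cases <- function(cases, n_reports = NA_integer_, cm, term,
                            fmt = icsr_format()) {
  stopifnot(inherits(cm, "class_map"))
  n <- nrow(cases)
  pct <- function(k, d) 100 * k / ifelse(d > 0, d, NA_real_)
  rng <- function(x) if (length(x)) c(min(x), max(x)) else c(NA_real_, NA_real_)

  if (n == 0) {
    out <- list(n_cases = 0L, n_reports = n_reports,
                term_code = term_code_of(term))
    class(out) <- "case_summary"
    return(out)
  }

  expo <- exposed_classes(cases, cm, fmt = fmt)
  mapped <- expo[expo$class_id != cm$unmapped_class, , drop = FALSE]
  n_vax <- length(unique(mapped$report_id))

  sex_known <- cases$sex[cases$sex %in% c("female", "male")]
  age <- cases$age_years[!is.na(cases$age_years)]

  # mention-level shares: each suspect drug entry resolving to a class
  dl <- icsr_drugs(cases, fmt)
  dl <- dl[dl$role == "suspect", , drop = FALSE]
  dl$class_id <- map_drug_class(dl$drug_name, cm, class_id = dl$class_id)
  mention <- dl[dl$class_id != cm$unmapped_class, , drop = FALSE]
  mention_counts <- table(mention$class_id)
  n_mentions <- sum(mention_counts)
  mention_shares <- tibble::tibble(
    class_id = names(mention_counts),
    mentions = as.integer(mention_counts),
    share_pct = pct(as.integer(mention_counts), n_mentions)
  ) |> dplyr::arrange(dplyr::desc(.data$mentions))

  tto_by_class <- lapply(unique(mapped$class_id), function(cl) {
    time_to_onset(cases, cl, term, cm, fmt)
  })
  tto <- if (length(tto_by_class)) {
    suppressWarnings(do.call(pmin, c(tto_by_class, list(na.rm = TRUE))))
  } else rep(NA_real_, n)
  tto <- tto[is.finite(tto)]

  ser <- unlist(strsplit(cases$seriousness[cases$seriousness != ""],
                         fmt$entry_sep, fixed = TRUE))
  seriousness_counts <- as.list(table(ser))

  outc <- table(factor(cases$outcome, levels = outcome_levels))
  outc_pct <- pct(as.integer(outc), n)
  outcome_counts <- tibble::tibble(
    outcome = names(outc), n = as.integer(outc), pct = outc_pct
  )

  ctry <- cases$country[!is.na(cases$country)]
  ctab <- sort(table(ctry), decreasing = TRUE)
  ctry_pct <- pct(as.integer(ctab), length(ctry))
  country_shares <- tibble::tibble(
    country = names(ctab), n = as.integer(ctab), share_pct = ctry_pct
  )

  out <- list(
    term_code = term_code_of(term),
    n_cases = n,
    n_reports = n_reports,
    n_vaccine_cases = n_vax,
    pct_vaccine_involved = pct(n_vax, n),
    n_sex_known = length(sex_known),
    pct_female = pct(sum(sex_known == "female"), length(sex_known)),
    n_age_known = length(age),
    median_age = if (length(age)) median(age) else NA_real_,
    age_range = rng(age),
    pct_age_lt15 = pct(sum(age < 15), length(age)),
    pct_age_15_30 = pct(sum(age >= 15 & age <= 30), length(age)),
    n_tto_known = length(tto),
    tto_median = if (length(tto)) median(tto) else NA_real_,
    tto_range = rng(tto),
    n_serious = sum(cases$seriousness != ""),
    seriousness_counts = seriousness_counts,
    outcome_counts = outcome_counts,
    country_shares = country_shares,
    n_mentions = n_mentions,
    mention_shares = mention_shares
  )
  class(out) <- "case_summary"
  out
}

#' @describeIn summarize_cases Scalar statistics as a long tibble with
#'   explicit denominators.
#' @param x A `case_summary`.
#' @param ... Unused.
#' @method tidy case_summary
#' @export
tidy.case_summary <- function(x, ...) {
  if (x$n_cases == 0) {
    return(tibble::tibble(statistic = "n_cases", value = 0,
                          denominator = NA_real_))
  }
  tibble::tibble(
    statistic = c("n_cases", "n_vaccine_cases", "pct_vaccine_involved",
                  "pct_female", "median_age", "age_min", "age_max",
                  "pct_age_lt15", "pct_age_15_30", "tto_median",
                  "tto_min", "tto_max", "n_serious"),
    value = c(x$n_cases, x$n_vaccine_cases, x$pct_vaccine_involved,
              x$pct_female, x$median_age, x$age_range[1], x$age_range[2],
              x$pct_age_lt15, x$pct_age_15_30, x$tto_median,
              x$tto_range[1], x$tto_range[2], x$n_serious),
    denominator = c(NA, NA, x$n_cases, x$n_sex_known, x$n_age_known,
                    NA, NA, x$n_age_known, x$n_age_known, x$n_tto_known,
                    NA, NA, x$n_cases)
  )
}

#' @describeIn summarize_cases One-row overview.
#' @method glance case_summary
#' @export
glance.case_summary <- function(x, ...) {
  tibble::tibble(
    term_code = x$term_code %||% NA_character_,
    n_cases = x$n_cases,
    n_reports = x$n_reports %||% NA,
    n_vaccine_cases = x$n_vaccine_cases %||% NA,
    pct_vaccine_involved = x$pct_vaccine_involved %||% NA,
    median_age = x$median_age %||% NA,
    tto_median = x$tto_median %||% NA
  )
}

#' @export
print.case_summary <- function(x, ...) {
  f1 <- function(v) ifelse(is.na(v), "NA", formatC(round(v, 1), format = "fg"))
  cat("Case series summary (term ", x$term_code, ")\n", sep = "")
  cat("  cases: ", x$n_cases,
      if (!is.na(x$n_reports %||% NA)) paste0(
        " of ", format(x$n_reports, big.mark = ","), " reports"), "\n",
      sep = "")
  if (x$n_cases == 0) return(invisible(x))
  cat("  vaccine involved: ", x$n_vaccine_cases, "/", x$n_cases,
      " (", f1(x$pct_vaccine_involved), "%)\n", sep = "")
  cat("  female: ", f1(x$pct_female), "% of ", x$n_sex_known,
      " with known sex\n", sep = "")
  cat("  age: median ", f1(x$median_age), " (range ",
      f1(x$age_range[1]), "-", f1(x$age_range[2]), "), <15y: ",
      f1(x$pct_age_lt15), "%, 15-30y: ", f1(x$pct_age_15_30),
      "% of ", x$n_age_known, " with known age\n", sep = "")
  cat("  time to onset: median ", f1(x$tto_median), " days (range ",
      f1(x$tto_range[1]), "-", f1(x$tto_range[2]), ") over ",
      x$n_tto_known, " cases\n", sep = "")
  cat("  serious: ", x$n_serious, "/", x$n_cases, "\n", sep = "")
  if (nrow(x$mention_shares)) {
    top <- head(x$mention_shares, 3)
    cat("  top suspect classes (", x$n_mentions, " mentions): ",
        paste0(top$class_id, " ", f1(top$share_pct), "%",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-class age profile of a case series
#'
#' Median and range of age over the case reports exposed to each class
#' (report-level exposure, suspect drugs only); classes with no
#' known-age exposed case are omitted. The even-`n` median is the
#' midpoint of the two central values.
#'
#' @param cases An ICSR tibble of case reports.
#' @param cm A [class_map()].
#' @param fmt An [icsr_format()].
#' @return Tibble with columns `class_id`, `n`, `median_age`, `age_min`,
#'   `age_max`.
#' @export
age_by_class <- function(cases, cm, fmt = icsr_format()) {
  expo <- exposed_classes(cases, cm, fmt = fmt)
  expo <- expo[expo$class_id != cm$unmapped_class, , drop = FALSE]
  ages <- tibble::tibble(report_id = cases$report_id,
                         age_years = cases$age_years)
  dplyr::inner_join(expo, ages, by = "report_id") |>
    dplyr::filter(!is.na(.data$age_years)) |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_age = median(.data$age_years),
      age_min = min(.data$age_years),
      age_max = max(.data$age_years),
      .groups = "drop"
    )
}

#' Write a case summary to JSON or a text report
#'
#' @param x A `case_summary`.
#' @param path Destination; `.json` writes JSON, anything else the
#'   printed text report.
#' @return `path`, invisibly.
#' @export
write_case_summary <- function(x, path) {
  stopifnot(inherits(x, "case_summary"))
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- unclass(x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    sink(con)
    print(x)
    sink()
  }
  invisible(path)
}
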