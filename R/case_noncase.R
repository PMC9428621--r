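#' Select the target adverse-event term
#'
#' Cases are reports coded with one specific dictionary term (for the
#' worked vaccine screen, the lowest-level term "Anti-NMDA receptor
#' encephalitis"). Matching is by exact term code, or by exact
#' case-insensitive term name when no code is given; no hierarchy
#' expansion is performed.
#'
#' @param code Term code to match exactly, or `NULL`.
#' @param name Term name to match exactly (case-insensitive), or `NULL`.
#' @return A list of class `term_selector`.
#' @export
term_selector <- function(code = NULL, name = NULL) {
  if (is.null(code) && is.null(name)) {
    abort_param("term_selector needs a code or a name")
  }
  structure(list(code = code, name = name), class = "term_selector")
}

as_term_selector <- function(term) {
  if (inherits(term, "term_selector")) return(term)
  if (is.character(term) && length(term) == 1) return(term_selector(code = term))
  abort_param("term must be a term_selector or a single term code")
}

term_code_of <- function(term) {
  term <- as_term_selector(term)
  term$code %||% term$name
}

#' Flag case reports for a target term
#'
#' A report is a case iff any of its event terms matches the selector;
#' listing the term twice on one report changes nothing (set semantics).
#'
#' @param reports An ICSR tibble.
#' @param term A [term_selector()] or a term code.
#' @param fmt An [icsr_format()].
#' @return Logical vector, one element per report row.
#' @export
is_case <- function(reports, term, fmt = icsr_format()) {
  term <- as_term_selector(term)
  if (!nrow(reports)) return(logical(0))
  ev <- icsr_events(reports, fmt)
  hit <- if (!is.null(term$code)) {
    ev$term_code == term$code
  } else {
    tolower(ev$term_name) == tolower(term$name)
  }
  hit_ids <- unique(ev$report_id[hit & !is.na(hit)])
  reports$report_id %in% hit_ids
}

#' Drug-class exposure of each report
#'
#' Exposure is counted at the report level: a report with two suspect
#' drugs of the same class is exposed to that class once. Suspect drugs
#' matching no class-map entry are recorded under the map's unmapped
#' class, never dropped.
#'
#' @param reports An ICSR tibble.
#' @param cm A [class_map()].
#' @param roles Drug roles counted as exposure (default suspect only).
#' @param fmt An [icsr_format()].
#' @return Tibble with columns `report_id`, `class_id`, one row per
#'   distinct (report, class) pair.
#' @export
exposed_classes <- function(reports, cm, roles = "suspect",
                            fmt = icsr_format()) {
  stopifnot(inherits(cm, "class_map"))
  dl <- icsr_drugs(reports, fmt)
  dl <- dl[dl$role %in% roles, , drop = FALSE]
  if (!nrow(dl)) {
    return(tibble::tibble(report_id = character(), class_id = character()))
  }
  dl$class_id <- map_drug_class(dl$drug_name, cm, class_id = dl$class_id)
  dplyr::distinct(dl[, c("report_id", "class_id")])
}

#' Split a report set into cases and non-cases
#'
#' The partition is disjoint and exhaustive: every report lands in
#' exactly one of the two sets.
#'
#' @inheritParams is_case
#' @return Named list with ICSR tibbles `cases` and `non_cases`.
#' @export
partition_cases <- function(reports, term, fmt = icsr_format()) {
  flag <- is_case(reports, term, fmt)
  list(cases = reports[flag, , drop = FALSE],
       non_cases = reports[!flag, , drop = FALSE])
}

#' Per-class 2x2 contingency tables for a case/non-case screen
#'
#' For each drug class the cells are counted over reports:
#' * `a` — case reports exposed to the class,
#' * `b` — non-case reports exposed to the class,
#' * `c` — case reports not exposed to the class,
#' * `d` — non-case reports not exposed to the class.
#'
#' The comparator is all other reports: `c` includes cases exposed to
#' other classes, and every class's four cells sum to the full report
#' count.
#'
#' @param reports An ICSR tibble.
#' @param term A [term_selector()] or term code.
#' @param cm A [class_map()].
#' @param classes Classes to tabulate; defaults to every class in `cm`.
#'   Unknown classes are a configuration error.
#' @param roles Drug roles counted as exposure.
#' @param fmt An [icsr_format()].
#' @return Tibble with columns `class_id`, `term_code`, `a`, `b`, `c`,
#'   `d`, one row per class.
#' @export
contingency_table <- function(reports, term, cm, classes = NULL,
                              roles = "suspect", fmt = icsr_format()) {
  stopifnot(inherits(cm, "class_map"))
  classes <- classes %||% class_ids(cm)
  unknown <- setdiff(classes, c(class_ids(cm), cm$unmapped_class))
  if (length(unknown)) {
    abort_config(paste0("class id(s) not in class map: ",
                        paste(unknown, collapse = ", ")))
  }
  n <- nrow(reports)
  flag <- is_case(reports, term, fmt)
  n_cases <- sum(flag)
  expo <- exposed_classes(reports, cm, roles = roles, fmt = fmt)
  expo$case <- expo$report_id %in% reports$report_id[flag]
  counts <- expo |>
    dplyr::filter(.data$class_id %in% classes) |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(a = sum(.data$case), b = sum(!.data$case),
                     .groups = "drop")
  out <- tibble::tibble(class_id = classes) |>
    dplyr::left_join(counts, by = "class_id") |>
    dplyr::mutate(
      a = dplyr::coalesce(.data$a, 0L),
      b = dplyr::coalesce(.data$b, 0L),
      term_code = term_code_of(term),
      c = n_cases - .data$a,
      d = n - n_cases - .data$b
    ) |>
    dplyr::select("class_id", "term_code", "a", "b", "c", "d")
  out
}

#' Contingency tables from published per-class counts
#'
#' Reconstructs the per-class 2x2 tables from exposed-case and
#' exposed-non-case counts plus the case and report totals, without
#' materialising any report rows (`c = n_cases - a`,
#' `d = n_reports - n_cases - b`). This is how a screen is reproduced
#' from a published count table for a database that cannot be
#' redistributed.
#'
#' @param counts Data frame with columns `class_id`, `a`, `b`.
#' @param n_cases Total number of case reports.
#' @param n_reports Total number of reports in the database.
#' @param term_code Term code recorded on the output rows.
#' @return Tibble with columns `class_id`, `term_code`, `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' counts <- anmdare_vaccine_counts()
#' contingency_from_counts(counts, n_cases = attr(counts, "n_cases"),
#'                         n_reports = attr(counts, "n_reports"))
contingency_from_counts <- function(counts, n_cases, n_reports,
                                    term_code = "TARGET") {
  counts <- tibble::as_tibble(counts)
  if (!all(c("class_id", "a", "b") %in% names(counts))) {
    abort_param("counts needs columns class_id, a, b")
  }
  a <- as.numeric(counts$a); b <- as.numeric(counts$b)
  if (any(a < 0 | b < 0 | a != round(a) | b != round(b))) {
    abort_param("counts a and b must be non-negative integers")
  }
  bad <- counts$class_id[a > n_cases]
  if (length(bad)) {
    abort_param(paste0("a exceeds n_cases for: ",
                       paste(bad, collapse = ", ")))
  }
  bad <- counts$class_id[b > n_reports - n_cases]
  if (length(bad)) {
    abort_param(paste0("b exceeds n_reports - n_cases for: ",
                       paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    class_id = counts$class_id,
    term_code = term_code,
    a = a, b = b,
    c = n_cases - a,
    d = n_reports - n_cases - b
  )
}
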