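#' Construct an ICSR line listing
#'
#' The package represents a set of individual case safety reports (ICSRs)
#' as a tibble with one row per report. Multi-valued fields (drugs, event
#' terms, seriousness criteria) are packed into sub-delimited character
#' cells so that a report set is a single flat, diffable table; the long
#' accessors [icsr_drugs()] and [icsr_events()] unnest them into tidy
#' relational tables for computation.
#'
#' Packed formats (defaults; see [icsr_format()]):
#' * `drugs`: `name|role|class_id|administration_date` entries joined by
#'   `;`. `role` is `suspect` or `concomitant`; `class_id` and the date
#'   may be empty.
#' * `events`: `term_code|term_name|onset_date` entries joined by `;`.
#' * `seriousness`: criteria joined by `;` (possibly empty = non-serious),
#'   each one of `death`, `life_threatening`, `hospitalization`,
#'   `disabling`, `congenital_anomaly`, `other_medically_important`.
#'
#' @param report_id Unique report identifiers (character).
#' @param drugs,events Packed character vectors (see above); each report
#'   needs at least one drug and one event.
#' @param age_years Age at onset in years (`NA` = unknown).
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param country ISO-3166 alpha-2 code or `NA`.
#' @param seriousness Packed seriousness criteria (`""` = none).
#' @param outcome One of `"recovered"`, `"recovering"`,
#'   `"not_recovered_or_sequelae"`, `"fatal"`, `"unknown"`.
#'
#' @return A tibble with class `icsr_tbl` prepended.
#' @seealso [validate_reports()], [read_icsr()], [pack_drugs()]
#' @export
icsr_reports <- function(report_id,
                         drugs,
                         events,
                         age_years = NA_real_,
                         sex = "unknown",
                         country = NA_character_,
                         seriousness = "",
                         outcome = "unknown") {
  out <- tibble::tibble(
    report_id = as.character(report_id),
    age_years = as.numeric(age_years),
    sex = as.character(sex),
    country = as.character(country),
    drugs = as.character(drugs),
    events = as.character(events),
    seriousness = as.character(seriousness),
    outcome = as.character(outcome)
  )
  dup <- unique(out$report_id[duplicated(out$report_id)])
  if (length(dup)) {
    abort_data(paste0(
      "duplicate report_id: ", paste(head(dup, 5), collapse = ", "),
      if (length(dup) > 5) ", ..."
    ))
  }
  class(out) <- c("icsr_tbl", class(out))
  out
}

icsr_columns <- c("report_id", "age_years", "sex", "country",
                  "drugs", "events", "seriousness", "outcome")

sex_levels <- c("female", "male", "unknown")
role_levels <- c("suspect", "concomitant")
outcome_levels <- c("recovered", "recovering", "not_recovered_or_sequelae",
                    "fatal", "unknown")
seriousness_levels <- c("death", "life_threatening", "hospitalization",
                        "disabling", "congenital_anomaly",
                        "other_medically_important")

#' Line-listing format configuration
#'
#' @param delim Column delimiter of the flat file.
#' @param entry_sep Separator between repeated entries inside a packed
#'   cell (drugs, events, seriousness).
#' @param field_sep Separator between fields of one packed entry.
#' @param columns Named character vector mapping the canonical column
#'   names to the file's header names.
#' @return A list of class `icsr_format`.
#' @export
icsr_format <- function(delim = ",", entry_sep = ";", field_sep = "|",
                        columns = NULL) {
  cols <- stats::setNames(icsr_columns, icsr_columns)
  if (!is.null(columns)) cols[names(columns)] <- columns
  structure(list(delim = delim, entry_sep = entry_sep,
                 field_sep = field_sep, columns = cols),
            class = "icsr_format")
}

unpack_entries <- function(packed, report_id, fields, fmt) {
  parts <- strsplit(packed, fmt$entry_sep, fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  if (!length(flat)) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(fields)), fields))
    return(dplyr::bind_cols(tibble::tibble(report_id = character()), out))
  }
  cells <- strsplit(flat, fmt$field_sep, fixed = TRUE)
  mat <- matrix("", nrow = length(cells), ncol = length(fields))
  for (j in seq_along(fields)) {
    mat[, j] <- vapply(cells, function(x) {
      if (length(x) >= j) x[[j]] else ""
    }, character(1))
  }
  out <- tibble::as_tibble(stats::setNames(
    lapply(seq_along(fields), function(j) mat[, j]), fields))
  dplyr::bind_cols(
    tibble::tibble(report_id = rep(report_id, n)), out
  )
}

#' Unnest packed drug entries into a long tibble
#'
#' @param reports An ICSR tibble.
#' @param fmt An [icsr_format()] giving the packing separators.
#' @return Tibble with columns `report_id`, `drug_name`, `role`,
#'   `class_id`, `administration_date` (Date, `NA` where absent).
#' @export
icsr_drugs <- function(reports, fmt = icsr_format()) {
  out <- unpack_entries(reports$drugs, reports$report_id,
                        c("drug_name", "role", "class_id",
                          "administration_date"), fmt)
  out$class_id[out$class_id == ""] <- NA_character_
  out$administration_date <- parse_iso_date(out$administration_date)
  out
}

#' Unnest packed event terms into a long tibble
#'
#' @inheritParams icsr_drugs
#' @return Tibble with columns `report_id`, `term_code`, `term_name`,
#'   `onset_date` (Date, `NA` where absent).
#' @export
icsr_events <- function(reports, fmt = icsr_format()) {
  out <- unpack_entries(reports$events, reports$report_id,
                        c("term_code", "term_name", "onset_date"), fmt)
  out$onset_date <- parse_iso_date(out$onset_date)
  out
}

parse_iso_date <- function(x) {
  x[x == ""] <- NA_character_
  as.Date(x, format = "%Y-%m-%d")
}

#' Pack a long drug table into line-listing cells
#'
#' Inverse of [icsr_drugs()]: groups a long table by `report_id` and
#' joins entries with the format separators.
#'
#' @param long Tibble with columns `report_id`, `drug_name`, `role`, and
#'   optionally `class_id`, `administration_date`.
#' @param fmt An [icsr_format()].
#' @return Named character vector of packed cells, one per report id.
#' @export
pack_drugs <- function(long, fmt = icsr_format()) {
  long <- tibble::as_tibble(long)
  cls <- if ("class_id" %in% names(long)) long$class_id else NA
  dt <- if ("administration_date" %in% names(long)) {
    long$administration_date
  } else NA
  entry <- paste(long$drug_name, long$role,
                 dplyr::coalesce(as.character(cls), ""),
                 dplyr::coalesce(as.character(dt), ""),
                 sep = fmt$field_sep)
  tapply_join(entry, long$report_id, fmt$entry_sep)
}

#' Pack a long event table into line-listing cells
#' @param long Tibble with columns `report_id`, `term_code`, `term_name`,
#'   and optionally `onset_date`.
#' @inheritParams pack_drugs
#' @return Named character vector of packed cells, one per report id.
#' @export
pack_events <- function(long, fmt = icsr_format()) {
  long <- tibble::as_tibble(long)
  dt <- if ("onset_date" %in% names(long)) long$onset_date else NA
  entry <- paste(long$term_code,
                 dplyr::coalesce(long$term_name, ""),
                 dplyr::coalesce(as.character(dt), ""),
                 sep = fmt$field_sep)
  tapply_join(entry, long$report_id, fmt$entry_sep)
}

tapply_join <- function(x, by, sep) {
  sp <- split(x, factor(by, levels = unique(by)))
  vapply(sp, paste, character(1), collapse = sep)
}

#' Validate an ICSR line listing
#'
#' Checks every structural invariant of the report model and reports
#' violations as data instead of raising: report ids unique and
#' non-empty, ages in \[0, 120\], sex/outcome/role/seriousness values in
#' their vocabularies, at least one drug and one event per report,
#' non-empty event term codes, and ISO-8601 dates. A total function:
#' arbitrary field values produce diagnostics, never an error.
#'
#' @param reports An ICSR tibble (or any data frame with its columns).
#' @param fmt An [icsr_format()].
#' @return Tibble with columns `report_id`, `field`, `message`; zero rows
#'   iff the listing is valid.
#' @export
validate_reports <- function(reports, fmt = icsr_format()) {
  v <- list()
  bad_row <- function(report_id, field, message) {
    tibble::tibble(report_id = as.character(report_id),
                   field = field, message = message)
  }
  id <- as.character(reports$report_id)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    v[[length(v) + 1]] <- bad_row(dup, "report_id", "duplicate report_id")
  }
  blank <- is.na(id) | id == ""
  if (any(blank)) {
    v[[length(v) + 1]] <- bad_row(id[blank], "report_id",
                                  "missing report_id")
  }
  age <- suppressWarnings(as.numeric(reports$age_years))
  bad <- !is.na(age) & (age < 0 | age > 120)
  if (any(bad)) {
    v[[length(v) + 1]] <- bad_row(id[bad], "age_years",
                                  "age_years outside [0, 120]")
  }
  bad <- !reports$sex %in% sex_levels
  if (any(bad)) {
    v[[length(v) + 1]] <- bad_row(id[bad], "sex",
                                  "sex not one of female/male/unknown")
  }
  bad <- !reports$outcome %in% outcome_levels
  if (any(bad)) {
    v[[length(v) + 1]] <- bad_row(
      id[bad], "outcome",
      paste0("outcome not one of ", paste(outcome_levels, collapse = "/"))
    )
  }
  bad <- is.na(reports$drugs) | reports$drugs == ""
  if (any(bad)) {
    v[[length(v) + 1]] <- bad_row(id[bad], "drugs",
                                  "report has no drug entries")
  }
  bad <- is.na(reports$events) | reports$events == ""
  if (any(bad)) {
    v[[length(v) + 1]] <- bad_row(id[bad], "events",
                                  "report has no event terms")
  }
  ok_rows <- !(is.na(reports$drugs) | reports$drugs == "")
  if (any(ok_rows)) {
    dl <- icsr_drugs(reports[ok_rows, , drop = FALSE], fmt)
    bad <- !dl$role %in% role_levels
    if (any(bad)) {
      v[[length(v) + 1]] <- bad_row(unique(dl$report_id[bad]), "drugs",
                                    "drug role not suspect/concomitant")
    }
  }
  ok_rows <- !(is.na(reports$events) | reports$events == "")
  if (any(ok_rows)) {
    el <- icsr_events(reports[ok_rows, , drop = FALSE], fmt)
    bad <- is.na(el$term_code) | el$term_code == ""
    if (any(bad)) {
      v[[length(v) + 1]] <- bad_row(unique(el$report_id[bad]), "events",
                                    "empty event term_code")
    }
  }
  ser <- strsplit(dplyr::coalesce(as.character(reports$seriousness), ""),
                  fmt$entry_sep, fixed = TRUE)
  bad <- vapply(ser, function(x) any(!x %in% seriousness_levels),
                logical(1))
  if (any(bad)) {
    v[[length(v) + 1]] <- bad_row(id[bad], "seriousness",
                                  "unknown seriousness criterion")
  }
  if (!length(v)) {
    return(tibble::tibble(report_id = character(), field = character(),
                          message = character()))
  }
  dplyr::distinct(dplyr::bind_rows(v))
}

#' Read an ICSR line listing from delimited text
#'
#' Rows that violate the report model are rejected with row-level
#' diagnostics (attached as the `"diagnostics"` attribute and summarised
#' in a warning); duplicated report ids are a hard data error.
#'
#' @param path File path of the delimited listing.
#' @param fmt An [icsr_format()] describing delimiters and header names.
#' @return A validated ICSR tibble.
#' @export
read_icsr <- function(path, fmt = icsr_format()) {
  if (!file.exists(path)) {
    abort_config(paste0("input file not found: ", path))
  }
  raw <- utils::read.delim(path, sep = fmt$delim, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  missing <- setdiff(unname(fmt$columns), names(raw))
  if (length(missing)) {
    abort_config(paste0("missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  }
  raw <- raw[, unname(fmt$columns), drop = FALSE]
  names(raw) <- names(fmt$columns)
  raw$age_years <- suppressWarnings(as.numeric(
    ifelse(raw$age_years == "", NA, raw$age_years)))
  raw$country[raw$country == ""] <- NA_character_
  dup <- unique(raw$report_id[duplicated(raw$report_id)])
  if (length(dup)) {
    abort_data(paste0("duplicate report_id in ", path, ": ",
                      paste(head(dup, 10), collapse = ", ")),
               duplicates = dup)
  }
  rs <- tibble::as_tibble(raw)
  diag <- validate_reports(rs, fmt)
  if (nrow(diag)) {
    keep <- !rs$report_id %in% diag$report_id
    warn(paste0(sum(!keep), " report(s) rejected by validation; ",
                "see attr(x, 'diagnostics')"))
    rs <- rs[keep, , drop = FALSE]
  }
  class(rs) <- c("icsr_tbl", class(rs))
  attr(rs, "diagnostics") <- diag
  rs
}

#' Write an ICSR line listing to delimited text
#'
#' The output round-trips: reading it back with the same format yields a
#' field-identical report table. An empty set writes the header only.
#'
#' @param reports An ICSR tibble.
#' @param path Destination path.
#' @param fmt An [icsr_format()].
#' @return `path`, invisibly.
#' @export
write_icsr <- function(reports, path, fmt = icsr_format()) {
  out <- as.data.frame(reports)[, icsr_columns, drop = FALSE]
  names(out) <- unname(fmt$columns[icsr_columns])
  out$age_years <- ifelse(is.na(out$age_years), "",
                          format(out$age_years, trim = TRUE,
                                 scientific = FALSE))
  out$country[is.na(out$country)] <- ""
  ok <- tryCatch({
    utils::write.table(out, path, sep = fmt$delim, row.names = FALSE,
                       quote = TRUE, qmethod = "double", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write to ", path, ": ", conditionMessage(ok)),
          class = c("rorscreen_io_error", "rorscreen_error"))
  }
  invisible(path)
}
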