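#' Build a drug-to-class map
#'
#' A class map resolves free-text drug names to analysis classes (for a
#' vaccine screen, one class per coded active ingredient). Entries match a
#' drug name either exactly or by prefix; both are case-insensitive. Drugs
#' that carry an explicit `class_id` in the line listing bypass name
#' matching.
#'
#' @param entries Data frame with columns `pattern`, `class_id` and
#'   optionally `match` (`"exact"` or `"prefix"`; default `"exact"`).
#' @param labels Optional data frame with columns `class_id`, `label`
#'   giving display names. Classes without a label use their `class_id`.
#' @param unmapped_class Class recorded for suspect drugs that match no
#'   entry; such drugs are never silently dropped.
#'
#' @return An object of class `class_map`.
#' @export
#' @examples
#' cm <- class_map(
#'   tibble::tibble(
#'     pattern = c("gardasil", "cervarix", "influenza vaccine"),
#'     class_id = c("HPV", "HPV", "INFLUENZA"),
#'     match = c("exact", "exact", "prefix")
#'   )
#' )
#' map_drug_class(c("Gardasil", "influenza vaccine 2019", "aspirin"), cm)
class_map <- function(entries, labels = NULL, unmapped_class = "UNMAPPED") {
  entries <- tibble::as_tibble(entries)
  if (!all(c("pattern", "class_id") %in% names(entries))) {
    abort_config("class map entries need columns 'pattern' and 'class_id'")
  }
  if (!"match" %in% names(entries)) entries$match <- "exact"
  entries$match[is.na(entries$match) | entries$match == ""] <- "exact"
  bad <- setdiff(unique(entries$match), c("exact", "prefix"))
  if (length(bad)) {
    abort_config(paste0("unknown match mode(s): ", paste(bad, collapse = ", ")))
  }
  ids <- unique(entries$class_id)
  if (is.null(labels)) {
    labels <- tibble::tibble(class_id = ids, label = ids)
  } else {
    labels <- tibble::as_tibble(labels)
    missing <- setdiff(ids, labels$class_id)
    if (length(missing)) {
      labels <- dplyr::bind_rows(
        labels, tibble::tibble(class_id = missing, label = missing)
      )
    }
  }
  structure(
    list(entries = entries, labels = labels, unmapped_class = unmapped_class),
    class = "class_map"
  )
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map> ", nrow(x$entries), " patterns -> ",
      length(unique(x$entries$class_id)), " classes\n", sep = "")
  print(x$entries, n = 10)
  invisible(x)
}

#' Class identifiers covered by a class map
#' @param cm A [class_map()].
#' @return Character vector of class ids in map order.
#' @export
class_ids <- function(cm) {
  stopifnot(inherits(cm, "class_map"))
  unique(cm$entries$class_id)
}

#' Display label for class ids
#' @param ids Character vector of class ids.
#' @param cm A [class_map()].
#' @return Character vector of labels (ids themselves where unlabelled).
#' @export
class_labels <- function(ids, cm) {
  stopifnot(inherits(cm, "class_map"))
  lab <- stats::setNames(cm$labels$label, cm$labels$class_id)
  out <- unname(lab[ids])
  ifelse(is.na(out), ids, out)
}

#' Resolve drug names to class ids
#'
#' Exact (case-insensitive) matches take precedence over prefix matches;
#' among prefix patterns the longest match wins. Names matching no pattern
#' resolve to the map's unmapped class.
#'
#' @param drug_name Character vector of drug names.
#' @param cm A [class_map()].
#' @param class_id Optional character vector of pre-coded class ids; where
#'   non-missing and non-empty these are used directly.
#' @return Character vector of class ids, same length as `drug_name`.
#' @export
map_drug_class <- function(drug_name, cm, class_id = NULL) {
  stopifnot(inherits(cm, "class_map"))
  lower <- tolower(trimws(drug_name))
  out <- rep(cm$unmapped_class, length(lower))

  exact <- cm$entries[cm$entries$match == "exact", ]
  if (nrow(exact)) {
    hit <- match(lower, tolower(exact$pattern))
    out[!is.na(hit)] <- exact$class_id[hit[!is.na(hit)]]
  }

  pref <- cm$entries[cm$entries$match == "prefix", ]
  if (nrow(pref)) {
    pref <- pref[order(-nchar(pref$pattern)), ]
    todo <- which(out == cm$unmapped_class)
    for (i in seq_len(nrow(pref))) {
      if (!length(todo)) break
      m <- startsWith(lower[todo], tolower(pref$pattern[i]))
      out[todo[m]] <- pref$class_id[i]
      todo <- todo[!m]
    }
  }

  if (!is.null(class_id)) {
    use <- !is.na(class_id) & class_id != ""
    out[use] <- class_id[use]
  }
  out
}

#' Read a class map from YAML, JSON or delimited text
#'
#' YAML/JSON files hold `entries` (list of `pattern`/`class_id`/`match`
#' records) and optional `labels`; CSV/TSV files hold the entries table
#' directly.
#'
#' @param path File path; format chosen by extension
#'   (`.yml`/`.yaml`, `.json`, else delimited).
#' @param unmapped_class Passed to [class_map()].
#' @return A [class_map()].
#' @export
read_class_map <- function(path, unmapped_class = "UNMAPPED") {
  if (!file.exists(path)) {
    abort_config(paste0("class map file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml", "json")) {
    raw <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    entries <- tibble::as_tibble(dplyr::bind_rows(raw$entries))
    labels <- if (!is.null(raw$labels)) {
      tibble::as_tibble(dplyr::bind_rows(raw$labels))
    }
    class_map(entries, labels, unmapped_class = unmapped_class)
  } else {
    delim <- if (ext == "tsv") "\t" else ","
    entries <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
    class_map(entries, unmapped_class = unmapped_class)
  }
}

#' Write a class map to YAML or JSON
#' @param cm A [class_map()].
#' @param path Destination; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(cm, path) {
  stopifnot(inherits(cm, "class_map"))
  obj <- list(
    entries = purrr::transpose(as.list(cm$entries)),
    labels = purrr::transpose(as.list(cm$labels))
  )
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
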