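#' Run the full screening pipeline on a line listing
#'
#' Reads a report listing and a class map, screens every class for the
#' target term, summarises the case series, and writes the artifacts to
#' `out_dir`: `signal_table.csv` (full precision),
#' `signal_table_display.csv` (display rounding), `signal_table.json`,
#' `case_summary.json`, `case_summary.txt`, and `manifest.json`
#' recording every parameter used, the input checksums and the package
#' version. Given identical inputs and parameters the run is fully
#' reproducible (no timestamps enter the outputs).
#'
#' @param input Path to the delimited line listing.
#' @param class_map_path Path to a class map file ([read_class_map()]).
#' @param term_code,term_name Target term; at least one required.
#' @param out_dir Output directory (created if needed).
#' @param min_exposed_cases,level Screen parameters (defaults 3, 0.95).
#' @param fmt An [icsr_format()].
#' @return Invisibly, a list with the `signal_screen`, the
#'   `case_summary` and the manifest.
#' @export
run_screen <- function(input, class_map_path, term_code = NULL,
                       term_name = NULL, out_dir = ".",
                       min_exposed_cases = 3, level = 0.95,
                       fmt = icsr_format()) {
  term <- term_selector(code = term_code, name = term_name)
  cm <- read_class_map(class_map_path)
  rs <- read_icsr(input, fmt)
  scr <- screen_signals(rs, term, cm, min_exposed_cases = min_exposed_cases,
                        level = level, fmt = fmt)
  cases <- rs[is_case(rs, term, fmt), , drop = FALSE]
  cs <- summarize_cases(cases, n_reports = nrow(rs), cm = cm, term = term,
                        fmt = fmt)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_signal_table(scr, file.path(out_dir, "signal_table.csv"))
  write_signal_table(scr, file.path(out_dir, "signal_table_display.csv"),
                     rounded = TRUE)
  write_signal_table(scr, file.path(out_dir, "signal_table.json"))
  write_case_summary(cs, file.path(out_dir, "case_summary.json"))
  write_case_summary(cs, file.path(out_dir, "case_summary.txt"))
  manifest <- run_manifest(
    command = "screen",
    inputs = c(input = input, class_map = class_map_path),
    params = list(term_code = term_code, term_name = term_name,
                  min_exposed_cases = min_exposed_cases, level = level)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(screen = scr, summary = cs, manifest = manifest))
}

#' Summarise the case series of a line listing
#'
#' The descriptive half of [run_screen()]: writes `case_summary.json`,
#' `case_summary.txt` and `manifest.json` only.
#'
#' @inheritParams run_screen
#' @return Invisibly, a list with the `case_summary` and the manifest.
#' @export
run_describe <- function(input, class_map_path, term_code = NULL,
                         term_name = NULL, out_dir = ".",
                         fmt = icsr_format()) {
  term <- term_selector(code = term_code, name = term_name)
  cm <- read_class_map(class_map_path)
  rs <- read_icsr(input, fmt)
  cases <- rs[is_case(rs, term, fmt), , drop = FALSE]
  cs <- summarize_cases(cases, n_reports = nrow(rs), cm = cm, term = term,
                        fmt = fmt)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_case_summary(cs, file.path(out_dir, "case_summary.json"))
  write_case_summary(cs, file.path(out_dir, "case_summary.txt"))
  manifest <- run_manifest(
    command = "describe",
    inputs = c(input = input, class_map = class_map_path),
    params = list(term_code = term_code, term_name = term_name)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = cs, manifest = manifest))
}

#' Generate a synthetic line listing to disk
#'
#' @param config Path to a YAML/JSON simulation config
#'   ([read_sim_config()]) or a [sim_config()] object.
#' @param out Path of the listing to write.
#' @param seed Integer seed; identical (config, seed) pairs write
#'   byte-identical files.
#' @param fmt An [icsr_format()].
#' @return Invisibly, the generated ICSR tibble.
#' @export
run_simulate <- function(config, out, seed = 1, fmt = icsr_format()) {
  cfg <- if (inherits(config, "sim_config")) config else
    read_sim_config(config)
  rs <- simulate_reports(cfg, seed = seed, fmt = fmt)
  write_icsr(rs, out, fmt)
  manifest <- run_manifest(
    command = "simulate",
    inputs = c(config = if (is.character(config)) config else NA),
    params = list(seed = seed, n_reports = cfg$n_reports)
  )
  jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rs)
}

#' Read a simulation config from YAML or JSON
#'
#' Top-level keys mirror the arguments of [sim_config()]; `classes` is a
#' list of records with `class_id`, `prevalence`, `rr` and optional
#' `age_profile`. Omitted keys keep their defaults.
#'
#' @param path File path (`.json` for JSON, else YAML).
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("sim config file not found: ", path))
  }
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw
  if (!is.null(raw$classes)) {
    args$classes <- tibble::as_tibble(dplyr::bind_rows(raw$classes))
    if (!"rr" %in% names(args$classes)) args$classes$rr <- 1
  }
  for (nm in c("country_weights", "seriousness_probs", "outcome_weights")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, args)
}

run_manifest <- function(command, inputs, params) {
  inputs <- inputs[!is.na(inputs)]
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(unname(unlist(inputs))))
  } else list()
  list(
    tool = "rorscreen",
    version = as.character(utils::packageVersion("rorscreen")),
    command = command,
    inputs = as.list(inputs),
    input_md5 = checksums,
    parameters = params
  )
}
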