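#' Reporting odds ratio
#'
#' The reporting odds ratio (ROR) of a case/non-case 2x2 table is
#' `a*d / (b*c)`: the odds of exposure among reports of the event of
#' interest relative to the exposure odds among all other reports. It
#' measures disproportionate reporting, not causal risk.
#'
#' Zero cells make the ratio (or its variance) undefined. The default
#' policy is to refuse with an error naming the offending cell; the
#' Haldane–Anscombe correction (`zero_cell = "haldane"`, +0.5 to every
#' cell) and silent `NA` (`zero_cell = "na"`, for batch screens) are
#' available.
#'
#' @param a,b,c,d Cell counts: exposed cases, exposed non-cases,
#'   unexposed cases, unexposed non-cases. Vectorised.
#' @param zero_cell One of `"error"`, `"haldane"`, `"na"`.
#' @return Numeric vector of RORs.
#' @export
#' @examples
#' ror(8, 116283, 62, 29642384) # 32.89
ror <- function(a, b, c, d, zero_cell = c("error", "haldane", "na")) {
  zero_cell <- match.arg(zero_cell)
  cl <- check_cells(a, b, c, d)
  z <- apply_zero_cell(cl$a, cl$b, cl$c, cl$d, zero_cell, need = c("b", "c"))
  (z$a * z$d) / (z$b * z$c)
}

#' Woolf (log-normal) confidence interval for the ROR
#'
#' `exp(log(ROR) +/- z * s)` with `s = sqrt(1/a + 1/b + 1/c + 1/d)` and
#' `z` the standard-normal quantile at `(1 + level) / 2`. The interval is
#' symmetric on the log scale, so `low * high = ROR^2`.
#'
#' @inheritParams ror
#' @param level Confidence level in (0, 1).
#' @return Tibble with columns `conf_low`, `conf_high`.
#' @export
#' @examples
#' ror_ci(8, 116283, 62, 29642384) # 15.8 to 68.7
ror_ci <- function(a, b, c, d, level = 0.95,
                   zero_cell = c("error", "haldane", "na")) {
  zero_cell <- match.arg(zero_cell)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort_param("level must be a single number in (0, 1)")
  }
  cl <- check_cells(a, b, c, d)
  z <- apply_zero_cell(cl$a, cl$b, cl$c, cl$d, zero_cell,
                       need = c("a", "b", "c", "d"))
  est <- log((z$a * z$d) / (z$b * z$c))
  s <- sqrt(1 / z$a + 1 / z$b + 1 / z$c + 1 / z$d)
  q <- qnorm((1 + level) / 2)
  tibble::tibble(conf_low = exp(est - q * s), conf_high = exp(est + q * s))
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Upper-tail probability at the Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom,
#' without continuity correction.
#'
#' @inheritParams ror
#' @return Numeric vector of p-values.
#' @export
#' @examples
#' chisq_p(4, 2881218, 66, 26877449) # 0.262
chisq_p <- function(a, b, c, d, zero_cell = c("error", "haldane", "na")) {
  zero_cell <- match.arg(zero_cell)
  cl <- check_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  margins_ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  if (any(!margins_ok)) {
    if (zero_cell == "error") {
      abort_param("zero margin: chi-square statistic undefined")
    }
    # haldane on the cells also repairs the margins
    if (zero_cell == "haldane") {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
      n <- a + b + c + d
      margins_ok <- rep(TRUE, length(n))
    }
  }
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  out <- pchisq(stat, df = 1, lower.tail = FALSE)
  out[!margins_ok] <- NA_real_
  out
}

# validates counts and returns them as doubles (integer cells overflow
# the products in the statistics at database scale)
check_cells <- function(a, b, c, d) {
  cells <- list(a = a, b = b, c = c, d = d)
  for (nm in names(cells)) {
    x <- cells[[nm]]
    if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
      abort_param(paste0("cell '", nm,
                         "' must be a non-negative integer count"))
    }
  }
  lapply(cells, as.numeric)
}

apply_zero_cell <- function(a, b, c, d, policy, need) {
  cells <- list(a = a, b = b, c = c, d = d)
  zero <- Reduce(`|`, lapply(need, function(nm) cells[[nm]] == 0))
  if (any(zero)) {
    if (policy == "error") {
      nm <- need[vapply(need, function(nm) any(cells[[nm]] == 0),
                        logical(1))]
      abort_param(paste0("zero cell(s) ", paste(nm, collapse = ", "),
                         ": result undefined (see zero_cell policy)"))
    }
    if (policy == "haldane") {
      cells <- lapply(cells, function(x) x + ifelse(zero, 0.5, 0))
    } else {
      cells <- lapply(cells, function(x) {
        x[zero] <- NA_real_
        x
      })
    }
  }
  cells
}

#' Screen per-class contingency tables for disproportionality signals
#'
#' Core screening step on an already-built contingency table: applies the
#' minimum exposed-case filter, computes ROR, Woolf confidence interval
#' and Pearson chi-square p-value for the evaluable rows, and flags a
#' signal where the lower confidence bound exceeds 1. Excluded rows keep
#' their counts but carry no statistics. No multiplicity adjustment is
#' applied; the row ordering (included by descending ROR, excluded last)
#' is presentation only.
#'
#' @param ctab Contingency tibble from [contingency_table()] or
#'   [contingency_from_counts()].
#' @param min_exposed_cases Minimum `a` for a class to be evaluable
#'   (default 3, the conventional minimum-count filter).
#' @param level Confidence level for the interval (default 0.95).
#' @param zero_cell Policy for zero cells in evaluable rows; see [ror()].
#' @param labels Optional [class_map()] used for display labels.
#' @return An object of class `signal_screen`; see [tidy.signal_screen()].
#' @export
screen_counts <- function(ctab, min_exposed_cases = 3, level = 0.95,
                          zero_cell = c("error", "haldane", "na"),
                          labels = NULL) {
  zero_cell <- match.arg(zero_cell)
  if (min_exposed_cases < 1) {
    abort_param("min_exposed_cases must be >= 1")
  }
  ctab <- tibble::as_tibble(ctab)
  res <- ctab |>
    dplyr::mutate(included = .data$a >= min_exposed_cases,
                  ror = NA_real_, conf_low = NA_real_,
                  conf_high = NA_real_, p_value = NA_real_)
  inc <- which(res$included)
  if (length(inc)) {
    res$ror[inc] <- ror(res$a[inc], res$b[inc], res$c[inc], res$d[inc],
                        zero_cell = zero_cell)
    ci <- ror_ci(res$a[inc], res$b[inc], res$c[inc], res$d[inc],
                 level = level, zero_cell = zero_cell)
    res$conf_low[inc] <- ci$conf_low
    res$conf_high[inc] <- ci$conf_high
    res$p_value[inc] <- chisq_p(res$a[inc], res$b[inc], res$c[inc],
                                res$d[inc], zero_cell = zero_cell)
  }
  res <- res |>
    dplyr::mutate(
      signal = .data$included & !is.na(.data$conf_low) & .data$conf_low > 1,
      status = classify_signal(.data$included, .data$conf_low),
      label = if (!is.null(labels)) {
        class_labels(.data$class_id, labels)
      } else .data$class_id
    ) |>
    dplyr::arrange(dplyr::desc(.data$included),
                   dplyr::desc(dplyr::coalesce(.data$ror, -Inf)),
                   dplyr::desc(.data$a)) |>
    dplyr::select("class_id", "label", "term_code", "a", "b", "c", "d",
                  "ror", "conf_low", "conf_high", "p_value",
                  "included", "signal", "status")
  structure(
    list(
      result = res,
      term_code = if (nrow(ctab)) ctab$term_code[[1]] else NA_character_,
      n_reports = if (nrow(ctab)) ctab$a[1] + ctab$b[1] + ctab$c[1] + ctab$d[1] else 0,
      n_cases = if (nrow(ctab)) ctab$a[1] + ctab$c[1] else 0,
      min_exposed_cases = min_exposed_cases,
      level = level,
      zero_cell = zero_cell,
      note = "No multiple-testing adjustment applied."
    ),
    class = "signal_screen"
  )
}

#' Run a full case/non-case disproportionality screen
#'
#' End-to-end screen over a report table: select cases by term, build the
#' per-class 2x2 tables at report level, and screen them with
#' [screen_counts()].
#'
#' @inheritParams contingency_table
#' @inheritParams screen_counts
#' @return An object of class `signal_screen`.
#' @export
#' @examples
#' cm <- class_map(tibble::tibble(pattern = "hpv vaccine", class_id = "HPV"))
#' rs <- icsr_reports(
#'   report_id = c("r1", "r2", "r3", "r4"),
#'   drugs = c("hpv vaccine|suspect||", "hpv vaccine|suspect||",
#'             "aspirin|suspect||", "aspirin|suspect||"),
#'   events = c("E1|target|", "E2|other|", "E1|target|", "E2|other|")
#' )
#' screen_signals(rs, "E1", cm, min_exposed_cases = 1)
screen_signals <- function(reports, term, cm, min_exposed_cases = 3,
                           level = 0.95,
                           zero_cell = c("error", "haldane", "na"),
                           roles = "suspect", fmt = icsr_format()) {
  ctab <- contingency_table(reports, term, cm, roles = roles, fmt = fmt)
  screen_counts(ctab, min_exposed_cases = min_exposed_cases, level = level,
                zero_cell = zero_cell, labels = cm)
}

#' Classify screened rows
#'
#' `not_evaluable` below the minimum-count filter; `signal` where the
#' lower confidence bound exceeds 1; `no_signal` otherwise.
#'
#' @param included Logical: passed the minimum exposed-case filter.
#' @param conf_low Lower confidence bound of the ROR (`NA` allowed).
#' @return Character vector over
#'   `c("signal", "no_signal", "not_evaluable")`.
#' @export
classify_signal <- function(included, conf_low) {
  dplyr::case_when(
    !included ~ "not_evaluable",
    !is.na(conf_low) & conf_low > 1 ~ "signal",
    .default = "no_signal"
  )
}

#' @describeIn screen_counts Full-precision per-class results as a tibble.
#' @param x A `signal_screen`.
#' @param ... Unused.
#' @method tidy signal_screen
#' @export
tidy.signal_screen <- function(x, ...) {
  x$result
}

#' @describeIn screen_counts One-row screen summary.
#' @method glance signal_screen
#' @export
glance.signal_screen <- function(x, ...) {
  tibble::tibble(
    term_code = x$term_code,
    n_reports = x$n_reports,
    n_cases = x$n_cases,
    n_classes = nrow(x$result),
    n_included = sum(x$result$included),
    n_signals = sum(x$result$signal),
    min_exposed_cases = x$min_exposed_cases,
    level = x$level
  )
}

#' Display rounding used in screen printouts
#'
#' RORs are shown to 2 decimal places, confidence bounds to 3 significant
#' figures, p-values to 3 decimals with values below 0.0005 shown as
#' `"<0.001"`.
#'
#' @param x A `signal_screen`.
#' @return Tibble of display-formatted columns alongside the counts.
#' @export
format_signal_table <- function(x) {
  stopifnot(inherits(x, "signal_screen"))
  r <- x$result
  fmt_num <- function(v, f) ifelse(is.na(v), "", f(v))
  tibble::tibble(
    class = r$label,
    a = r$a, b = r$b,
    ROR = fmt_num(r$ror, function(v) formatC(round(v, 2), format = "fg")),
    `95% CI` = ifelse(is.na(r$conf_low), "", paste0(
      "[", signif(r$conf_low, 3), "-", signif(r$conf_high, 3), "]")),
    p = fmt_num(r$p_value, function(v) {
      ifelse(v < 5e-4, "<0.001", formatC(round(v, 3), format = "fg"))
    }),
    status = r$status
  )
}

#' @export
print.signal_screen <- function(x, ...) {
  cat("Case/non-case disproportionality screen\n")
  cat("  term: ", x$term_code,
      "   reports: ", format(x$n_reports, big.mark = ","),
      "   cases: ", format(x$n_cases, big.mark = ","), "\n", sep = "")
  cat("  filter: a >= ", x$min_exposed_cases,
      "   CI level: ", x$level, "\n", sep = "")
  print(format_signal_table(x), n = nrow(x$result))
  cat(x$note, "\n")
  invisible(x)
}

#' Forest plot of a disproportionality screen
#'
#' Evaluable classes are drawn on a log ROR axis with their confidence
#' intervals; the vertical line at 1 marks no disproportionality.
#'
#' @param object A `signal_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_screen
#' @export
autoplot.signal_screen <- function(object, ...) {
  dat <- dplyr::filter(object$result, .data$included, !is.na(.data$ror))
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ror, y = .data$label,
                                    colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (log scale)", y = NULL,
                  colour = "Signal",
                  title = paste0("Disproportionality screen: ",
                                 object$term_code)) +
    ggplot2::theme_minimal()
}

#' Write a screen result to delimited text or JSON
#'
#' @param x A `signal_screen`.
#' @param path Destination; `.json` writes JSON, anything else CSV.
#' @param rounded Write the display-rounded table instead of full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(x, path, rounded = FALSE) {
  stopifnot(inherits(x, "signal_screen"))
  out <- if (rounded) format_signal_table(x) else tidy(x)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(summary = as.list(glance(x)), note = x$note, rows = out),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
  } else {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
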