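#' Operating characteristics of the screen by simulation
#'
#' Repeatedly generates a synthetic database from `cfg` and screens it,
#' then aggregates per-class flag frequencies. Two error rates are
#' reported: the two-sided rejection rate (confidence interval excludes
#' 1), whose nominal level under a null class is `1 - level`, and the
#' directional signal rate (lower bound above 1), which under a null
#' class runs at about half that. Replicate `i` uses seed `seed + i`, so
#' the whole evaluation is deterministic given (`seed`, `replicates`).
#'
#' @param cfg A [sim_config()].
#' @param replicates Number of simulated databases (>= 1).
#' @param seed Base integer seed.
#' @param min_exposed_cases,level Screen parameters (defaults 3, 0.95).
#' @param method `"counts"` draws the per-class 2x2 cells from the exact
#'   count distribution ([simulate_counts()]); `"reports"` materialises
#'   every report ([simulate_reports()]) and runs the full pipeline.
#'   The two agree in distribution; `"counts"` is the practical choice
#'   for database-scale replicates.
#' @return An object of class `oc_eval`: per-class rates, overall
#'   type-I error (two-sided, null classes) and power (signal rate,
#'   non-null classes).
#' @export
evaluate_oc <- function(cfg, replicates, seed = 1,
                        min_exposed_cases = 3, level = 0.95,
                        method = c("counts", "reports")) {
  stopifnot(inherits(cfg, "sim_config"))
  method <- match.arg(method)
  if (replicates < 1) abort_param("replicates must be >= 1")

  cl <- cfg$classes
  cm <- sim_class_map(cl)
  k <- nrow(cl)
  n_eval <- sig_flag <- reject <- numeric(k)

  for (i in seq_len(replicates)) {
    rep_seed <- seed + i
    scr <- if (method == "counts") {
      sim <- simulate_counts(cfg, seed = rep_seed)
      ctab <- contingency_from_counts(sim$counts, sim$n_cases,
                                      sim$n_reports,
                                      term_code = cfg$target_code)
      screen_counts(ctab, min_exposed_cases = min_exposed_cases,
                    level = level, zero_cell = "na")
    } else {
      rs <- simulate_reports(cfg, seed = rep_seed)
      screen_signals(rs, term_selector(code = cfg$target_code), cm,
                     min_exposed_cases = min_exposed_cases,
                     level = level, zero_cell = "na")
    }
    res <- tidy(scr)
    res <- res[match(cl$class_id, res$class_id), ]
    ok <- res$included & !is.na(res$conf_low)
    n_eval <- n_eval + ok
    sig_flag <- sig_flag + (ok & res$conf_low > 1)
    reject <- reject + (ok & (res$conf_low > 1 | res$conf_high < 1))
  }

  per_class <- tibble::tibble(
    class_id = cl$class_id, rr = cl$rr,
    n_evaluable = as.integer(n_eval),
    signal_rate = ifelse(n_eval > 0, sig_flag / n_eval, NA_real_),
    reject_rate = ifelse(n_eval > 0, reject / n_eval, NA_real_)
  )
  null_cl <- cl$rr == 1
  out <- list(
    per_class = per_class,
    replicates = replicates,
    seed = seed,
    level = level,
    min_exposed_cases = min_exposed_cases,
    method = method,
    type1 = if (any(null_cl) && sum(n_eval[null_cl]) > 0) {
      sum(reject[null_cl]) / sum(n_eval[null_cl])
    } else NA_real_,
    signal_rate_null = if (any(null_cl) && sum(n_eval[null_cl]) > 0) {
      sum(sig_flag[null_cl]) / sum(n_eval[null_cl])
    } else NA_real_,
    power = if (any(!null_cl)) {
      sum(sig_flag[!null_cl]) / (replicates * sum(!null_cl))
    } else NA_real_
  )
  class(out) <- "oc_eval"
  out
}

#' @describeIn evaluate_oc Per-class rates as a tibble.
#' @param x An `oc_eval`.
#' @param ... Unused.
#' @method tidy oc_eval
#' @export
tidy.oc_eval <- function(x, ...) x$per_class

#' @describeIn evaluate_oc One-row summary.
#' @method glance oc_eval
#' @export
glance.oc_eval <- function(x, ...) {
  tibble::tibble(
    replicates = x$replicates, method = x$method, level = x$level,
    min_exposed_cases = x$min_exposed_cases,
    type1 = x$type1, signal_rate_null = x$signal_rate_null,
    power = x$power
  )
}

#' @export
print.oc_eval <- function(x, ...) {
  cat("Screen operating characteristics (", x$replicates,
      " replicates, method=", x$method, ")\n", sep = "")
  cat("  type-I error (two-sided, null classes): ",
      formatC(x$type1, digits = 3, format = "fg"),
      "  directional signal rate: ",
      formatC(x$signal_rate_null, digits = 3, format = "fg"), "\n",
      sep = "")
  if (!is.na(x$power)) {
    cat("  power (signal classes): ",
        formatC(x$power, digits = 3, format = "fg"), "\n", sep = "")
  }
  print(x$per_class)
  invisible(x)
}

#' Bar chart of per-class flag rates
#' @param object An `oc_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oc_eval
#' @export
autoplot.oc_eval <- function(object, ...) {
  dat <- object$per_class
  dat$null <- dat$rr == 1
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class_id,
                                    y = .data$signal_rate,
                                    fill = .data$null)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = (1 - object$level) / 2,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Signal flag rate",
                  fill = "Null class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write operating characteristics to delimited text
#' @param x An `oc_eval`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_oc <- function(x, path) {
  stopifnot(inherits(x, "oc_eval"))
  utils::write.csv(tidy(x), path, row.names = FALSE, na = "")
  invisible(path)
}
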