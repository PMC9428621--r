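# Independent direct-formula oracles for the 2x2 statistics. Kept free of
# any package internals: odds ratio as a ratio of odds, the interval from
# first principles on the log scale, and the chi-square p-value delegated
# to stats::chisq.test.

oracle_or <- function(a, b, c, d) {
  (a / c) / (b / d)
}

oracle_ci <- function(a, b, c, d, level = 0.95) {
  lo <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(exp(lo - z * se), exp(lo + z * se))
}

oracle_p <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
}

# random strictly-positive 2x2 tables
random_tables <- function(n, seed, max_cell = 1e6) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = sample.int(max_cell, n, replace = TRUE),
      b = sample.int(max_cell, n, replace = TRUE),
      c = sample.int(max_cell, n, replace = TRUE),
      d = sample.int(max_cell, n, replace = TRUE)
    )
  })
}
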