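test_that("published screen statistics reproduce to printed precision", {
  # HPV row
  expect_equal(round(ror(8, 116283, 62, 29642384), 2), 32.89)
  ci <- ror_ci(8, 116283, 62, 29642384)
  expect_equal(round(ci$conf_low, 1), 15.8)
  expect_equal(round(ci$conf_high, 1), 68.7)
  # DTP-polio row, abstract interval
  expect_equal(round(ror(8, 70006, 62, 29688661), 2), 54.72)
  ci <- ror_ci(8, 70006, 62, 29688661)
  expect_equal(round(ci$conf_low, 1), 26.2)
  expect_equal(round(ci$conf_high, 1), 114.3)
  # yellow fever and COVID-19 rows
  expect_equal(round(ror(3, 26614, 67, 29732053), 2), 50.02)
  expect_equal(round(ror(4, 2881218, 66, 26877449), 2), 0.57)
  expect_equal(round(chisq_p(4, 2881218, 66, 26877449), 3), 0.262)
  expect_lt(chisq_p(8, 116283, 62, 29642384), 0.001)
  # null table
  expect_equal(ror(1, 1, 1, 1), 1)
  expect_equal(chisq_p(1, 1, 1, 1), 1)
})

test_that("statistics agree with independent oracles on random tables", {
  tabs <- random_tables(1000, seed = 2024)
  est <- ror(tabs$a, tabs$b, tabs$c, tabs$d)
  ci <- ror_ci(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- chisq_p(tabs$a, tabs$b, tabs$c, tabs$d)
  for (i in seq_len(nrow(tabs))) {
    o_or <- oracle_or(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    o_ci <- oracle_ci(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    o_p <- oracle_p(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(est[i], o_or, tolerance = 1e-9)
    expect_equal(ci$conf_low[i], o_ci[1], tolerance = 1e-9)
    expect_equal(ci$conf_high[i], o_ci[2], tolerance = 1e-9)
    expect_equal(p[i], o_p, tolerance = 1e-9)
  }
})

test_that("interval is log-symmetric and consistent with a Wald test", {
  tabs <- random_tables(200, seed = 7)
  est <- ror(tabs$a, tabs$b, tabs$c, tabs$d)
  ci <- ror_ci(tabs$a, tabs$b, tabs$c, tabs$d)
  # low * high = ror^2 (log-symmetry of the Woolf interval)
  expect_equal(ci$conf_low * ci$conf_high, est^2,
               tolerance = 1e-9)
  # CI excludes 1 exactly when the two-sided Wald z-test rejects
  se <- sqrt(1 / tabs$a + 1 / tabs$b + 1 / tabs$c + 1 / tabs$d)
  wald_sig <- abs(log(est)) / se > qnorm(0.975)
  ci_excl <- ci$conf_low > 1 | ci$conf_high < 1
  expect_identical(ci_excl, wald_sig)
})

test_that("ROR obeys transpose and reciprocity symmetries", {
  tabs <- random_tables(100, seed = 11)
  est <- ror(tabs$a, tabs$b, tabs$c, tabs$d)
  # exchanging b and c leaves ad/bc unchanged
  expect_equal(ror(tabs$a, tabs$c, tabs$b, tabs$d), est)
  # chi-square invariant under margin-preserving transposes
  expect_equal(chisq_p(tabs$a, tabs$c, tabs$b, tabs$d),
               chisq_p(tabs$a, tabs$b, tabs$c, tabs$d))
  # swapping exposure labels inverts the ROR and mirrors the interval
  ci <- ror_ci(tabs$a, tabs$b, tabs$c, tabs$d)
  swapped <- ror_ci(tabs$c, tabs$d, tabs$a, tabs$b)
  expect_equal(ror(tabs$c, tabs$d, tabs$a, tabs$b), 1 / est,
               tolerance = 1e-12)
  expect_equal(swapped$conf_low, 1 / ci$conf_high, tolerance = 1e-12)
  expect_equal(swapped$conf_high, 1 / ci$conf_low, tolerance = 1e-12)
})

test_that("zero cells follow the declared policy", {
  err <- expect_error(ror(3, 0, 5, 10), class = "rorscreen_param_error")
  expect_match(conditionMessage(err), "b")
  expect_true(is.na(ror(3, 0, 5, 10, zero_cell = "na")))
  # Haldane: +0.5 everywhere
  expect_equal(ror(3, 0, 5, 10, zero_cell = "haldane"),
               (3.5 * 10.5) / (0.5 * 5.5))
  expect_error(ror(-1, 1, 1, 1), class = "rorscreen_param_error")
  expect_error(ror_ci(1, 1, 1, 1, level = 1.2),
               class = "rorscreen_param_error")
})

test_that("screening applies the minimum-count filter and orders rows", {
  scr <- screen_counts(published_ctab())
  res <- tidy(scr)
  expect_identical(sum(res$included), 8L)
  expect_setequal(res$class_id[!res$included],
                  c("RABIES", "TYPHOID", "HEP_AB", "HEP_A", "HEP_B"))
  expect_true(all(is.na(res$ror[!res$included])))
  expect_identical(res$status[!res$included],
                   rep("not_evaluable", 5))
  # sorted by descending ROR among included, excluded last
  expect_false(is.unsorted(rev(res$ror[res$included])))
  expect_identical(res$class_id[1], "DTP_POLIO")
  # signal = lower bound above 1; COVID-19 is the lone evaluable no-signal
  expect_identical(res$status[res$class_id == "COVID19"], "no_signal")
  expect_identical(sum(res$signal), 7L)
  # relaxing the filter only adds rows (monotonicity)
  res1 <- tidy(screen_counts(published_ctab(), min_exposed_cases = 1,
                             zero_cell = "na"))
  expect_identical(sum(res1$included), 13L)
  expect_true(all(res$class_id[res$included] %in%
                  res1$class_id[res1$included]))
})

test_that("classification distinguishes signal, no-signal, not-evaluable", {
  expect_identical(
    classify_signal(c(TRUE, TRUE, FALSE), c(15.8, 0.2, NA)),
    c("signal", "no_signal", "not_evaluable")
  )
})

test_that("screen objects expose tidy, glance, format and plot views", {
  counts <- anmdare_vaccine_counts()
  label_map <- class_map(
    tibble::tibble(pattern = tolower(counts$label),
                   class_id = counts$class_id),
    labels = tibble::tibble(class_id = counts$class_id,
                            label = counts$label)
  )
  scr <- screen_counts(published_ctab(), labels = label_map)
  g <- glance(scr)
  expect_equal(g$n_reports, 29758737)
  expect_equal(g$n_cases, 70)
  expect_identical(g$n_included, 8L)
  disp <- format_signal_table(scr)
  expect_identical(disp$ROR[disp$class == "HPV vaccine"], "32.89")
  expect_identical(disp$p[disp$class == "HPV vaccine"], "<0.001")
  expect_identical(disp$p[disp$class == "COVID-19 vaccine"], "0.262")
  expect_s3_class(autoplot(scr), "ggplot")
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(scr, f)
  expect_identical(nrow(utils::read.csv(f)), 13L)
})
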