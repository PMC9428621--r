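test_that("generator is deterministic and honours n_reports", {
  cfg <- sim_config(n_reports = 500, background_event_prob = 0.01)
  a <- simulate_reports(cfg, seed = 5)
  b <- simulate_reports(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_reports(cfg, seed = 6)))
  expect_identical(nrow(a), 500L)

  empty <- simulate_reports(sim_config(n_reports = 0), seed = 1)
  expect_identical(nrow(empty), 0L)

  # byte-identical serialisation for identical (config, seed)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_icsr(a, f1); write_icsr(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated reports validate and cover the configured vocabularies", {
  cfg <- sim_config(n_reports = 300, background_event_prob = 0.05)
  rs <- simulate_reports(cfg, seed = 2)
  expect_identical(nrow(validate_reports(rs)), 0L)
  # onset lags are capped
  cm <- sim_class_map()
  cases <- rs[is_case(rs, TARGET), ]
  for (cl in unique(exposed_classes(cases, cm)$class_id)) {
    if (cl == "UNMAPPED") next
    tto <- suppressWarnings(time_to_onset(cases, cl, TARGET, cm))
    expect_true(all(tto[!is.na(tto)] <= 730))
  }
})

test_that("null case counts match the binomial oracle", {
  # n * p = 100 expected cases; count must sit within 3 sd of it
  cfg <- sim_config(n_reports = 1e6, background_event_prob = 1e-4,
                    classes = tibble::tibble(class_id = "X",
                                             prevalence = 0.01, rr = 1))
  sim <- simulate_counts(cfg, seed = 9)
  expect_lt(abs(sim$n_cases - 100), 3 * sqrt(1e6 * 1e-4) + 1e-9)
  # exposure prevalence converges at 1/sqrt(n): within 4 se
  n_exposed <- sum(sim$counts$a + sim$counts$b)
  se <- sqrt(1e6 * 0.01 * 0.99)
  expect_lt(abs(n_exposed - 1e6 * 0.01), 4 * se)
})

test_that("row-level and count-level samplers agree in distribution", {
  cfg <- sim_config(n_reports = 5000, background_event_prob = 0.01,
                    classes = tibble::tibble(
                      class_id = c("S", "N"),
                      prevalence = c(0.05, 0.10),
                      rr = c(8, 1)))
  reps <- 60
  stats_of <- function(sim) c(sim$n_cases, sim$counts$a, sim$counts$b)
  rows <- vapply(seq_len(reps), function(i) {
    rs <- simulate_reports(cfg, seed = 100 + i)
    flag <- is_case(rs, TARGET)
    expo <- exposed_classes(rs, sim_class_map(cfg$classes))
    a <- vapply(c("S", "N"), function(cl) {
      sum(expo$class_id == cl &
            expo$report_id %in% rs$report_id[flag])
    }, numeric(1))
    b <- vapply(c("S", "N"), function(cl) {
      sum(expo$class_id == cl)
    }, numeric(1)) - a
    c(sum(flag), a, b)
  }, numeric(5))
  cnts <- vapply(seq_len(reps), function(i) {
    stats_of(simulate_counts(cfg, seed = 500 + i))
  }, numeric(5))
  # compare replicate means of every cell within 4 combined standard errors
  for (j in 1:5) {
    m1 <- mean(rows[j, ]); m2 <- mean(cnts[j, ])
    se <- sqrt(stats::var(rows[j, ]) / reps + stats::var(cnts[j, ]) / reps)
    expect_lt(abs(m1 - m2), 4 * se + 1e-9)
  }
})

test_that("count reconstruction is the identity on feasible specifications", {
  cm_classes <- c("K1", "K2", "K3")
  withr::with_seed(31, {
    for (rep in 1:10) {
      n_cases <- sample(5:40, 1)
      a <- sapply(cm_classes, function(x) sample(0:n_cases, 1))
      b <- sapply(cm_classes, function(x) sample(0:50, 1))
      n_reports <- n_cases + sum(b) + sample(0:100, 1)
      counts <- tibble::tibble(class_id = cm_classes, a = a, b = b)
      rs <- simulate_tabulated(counts, n_cases, n_reports)
      cm <- class_map(tibble::tibble(
        pattern = paste(tolower(cm_classes), "vaccine"),
        class_id = cm_classes))
      ct <- contingency_table(rs, TARGET, cm)
      ct <- ct[match(cm_classes, ct$class_id), ]
      expect_equal(as.numeric(ct$a), as.numeric(a), ignore_attr = TRUE)
      expect_equal(as.numeric(ct$b), as.numeric(b), ignore_attr = TRUE)
      expect_identical(nrow(rs), as.integer(n_reports))
    }
  })
})

test_that("infeasible count specifications are refused with the constraint", {
  expect_error(
    simulate_tabulated(tibble::tibble(class_id = "X", a = 10, b = 0),
                       n_cases = 5, n_reports = 100),
    regexp = "n_cases"
  )
  expect_error(
    simulate_tabulated(tibble::tibble(class_id = "X", a = 1, b = 200),
                       n_cases = 5, n_reports = 100),
    regexp = "n_reports - n_cases"
  )
  # packing constraint: cannot put 5 mentions of one class on 3 reports
  expect_error(
    simulate_tabulated(tibble::tibble(class_id = "X", a = 5, b = 0),
                       n_cases = 10, n_reports = 100,
                       n_exposed_cases = 3),
    regexp = "packed"
  )
})

test_that("virtual mode returns the contingency table without rows", {
  counts <- anmdare_vaccine_counts()
  ct <- simulate_tabulated(counts, attr(counts, "n_cases"),
                           attr(counts, "n_reports"),
                           materialize = FALSE)
  expect_s3_class(ct, "tbl_df")
  expect_identical(nrow(ct), 13L)
  hpv <- ct[ct$class_id == "HPV", ]
  expect_equal(c(hpv$a, hpv$b, hpv$c, hpv$d),
               c(8, 116283, 62, 29642384))
})

test_that("invalid simulation configs are rejected with reasons", {
  expect_error(sim_config(n_reports = -1), class = "rorscreen_param_error")
  expect_error(
    sim_config(classes = tibble::tibble(class_id = "X", prevalence = 1.5,
                                        rr = 1)),
    regexp = "prevalence"
  )
  expect_error(sim_config(background_event_prob = 2),
               class = "rorscreen_param_error")
})

test_that("operating characteristics are deterministic and bounded", {
  cfg <- sim_config(n_reports = 2e5, background_event_prob = 5e-4,
                    classes = tibble::tibble(class_id = c("A", "B"),
                                             prevalence = 0.1, rr = 1))
  oc1 <- evaluate_oc(cfg, replicates = 20, seed = 4)
  oc2 <- evaluate_oc(cfg, replicates = 20, seed = 4)
  expect_identical(tidy(oc1), tidy(oc2))
  expect_true(all(tidy(oc1)$signal_rate >= 0 &
                  tidy(oc1)$signal_rate <= 1, na.rm = TRUE))
  # single replicate yields degenerate frequencies
  oc3 <- evaluate_oc(cfg, replicates = 1, seed = 4)
  rates <- tidy(oc3)$signal_rate
  expect_true(all(rates %in% c(0, 1) | is.na(rates)))
  expect_s3_class(autoplot(oc1), "ggplot")
})
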