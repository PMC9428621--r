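test_that("case flagging matches by code or name, idempotently", {
  rs <- toy_reports()
  expect_identical(is_case(rs, TARGET), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(
    is_case(rs, term_selector(name = "anti-nmda RECEPTOR encephalitis")),
    c(TRUE, TRUE, FALSE, FALSE)
  )
  # the target term listed twice still flags once
  twice <- rs
  twice$events[1] <- paste(rs$events[1], rs$events[1], sep = ";")
  expect_identical(is_case(twice, TARGET), is_case(rs, TARGET))
  expect_identical(is_case(rs[0, ], TARGET), logical(0))
})

test_that("exposure is report-level, role-filtered, never dropped", {
  cm <- toy_class_map()
  rs <- icsr_reports(
    report_id = c("x1", "x2", "x3"),
    drugs = c(
      "Gardasil|suspect||;Cervarix|suspect||",          # two HPV suspects
      "Gardasil|suspect||;influenza vaccine|concomitant||",
      "mystery elixir|suspect||"
    ),
    events = rep("E|x|", 3)
  )
  expo <- exposed_classes(rs, cm)
  expect_identical(expo$class_id[expo$report_id == "x1"], "HPV")
  expect_identical(expo$class_id[expo$report_id == "x2"], "HPV")
  expect_identical(expo$class_id[expo$report_id == "x3"], "UNMAPPED")
  both <- exposed_classes(rs, cm, roles = c("suspect", "concomitant"))
  expect_setequal(both$class_id[both$report_id == "x2"],
                  c("HPV", "INFLUENZA"))
  none <- exposed_classes(rs, cm, roles = "concomitant")
  expect_false("x1" %in% none$report_id)
})

test_that("partition into cases and non-cases is disjoint and exhaustive", {
  rs <- toy_reports()
  p <- partition_cases(rs, TARGET)
  expect_identical(nrow(p$cases) + nrow(p$non_cases), nrow(rs))
  expect_length(intersect(p$cases$report_id, p$non_cases$report_id), 0)

  p0 <- partition_cases(rs, "LLT_NOWHERE")
  expect_identical(nrow(p0$cases), 0L)
  expect_identical(p0$non_cases$report_id, rs$report_id)

  all_case <- partition_cases(rs, term_selector(name = "headache"))
  expect_identical(nrow(all_case$non_cases), 2L)
})

test_that("a generator-constructed split of 70 cases in 29,000 is recovered", {
  counts <- tibble::tibble(class_id = "HPV", a = 8L, b = 115L)
  rs <- simulate_tabulated(counts, n_cases = 70, n_reports = 29000)
  p <- partition_cases(rs, TARGET)
  expect_identical(nrow(p$cases), 70L)
  expect_identical(nrow(p$non_cases), 28930L)
})

test_that("toy 2x2 and zero-exposure tables count correctly", {
  cm <- toy_class_map()
  ct <- contingency_table(toy_reports(), TARGET, cm, classes = "HPV")
  expect_equal(unlist(ct[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 1, 1, 1))
  ct2 <- contingency_table(toy_reports(), TARGET, cm,
                           classes = "DTP_POLIO")
  expect_equal(ct2$a, 0); expect_equal(ct2$b, 0)
  expect_error(contingency_table(toy_reports(), TARGET, cm,
                                 classes = "MARTIAN"),
               class = "rorscreen_config_error")
})

test_that("a scaled published reconstruction brute-force tallies to its spec", {
  counts <- anmdare_vaccine_counts()
  scaled <- counts
  scaled$b <- as.integer(round(counts$b / 1000)) # 116, 70, 281, ...
  n_rep <- 29759L
  rs <- simulate_tabulated(scaled, n_cases = 70, n_reports = n_rep,
                           n_exposed_cases = 29)
  cm <- sim_class_map()
  ct <- contingency_table(rs, TARGET, cm)
  ct <- ct[match(scaled$class_id, ct$class_id), ]
  expect_identical(as.integer(ct$a), scaled$a)
  expect_identical(as.integer(ct$b), scaled$b)
  # brute-force tally, independent of the counting pipeline
  case_flag <- grepl(TARGET, rs$events, fixed = TRUE)
  hpv_flag <- grepl("hpv vaccine", rs$drugs, fixed = TRUE)
  expect_identical(sum(case_flag & hpv_flag), 8L)
  expect_identical(sum(!case_flag & hpv_flag), 116L)
  expect_equal(ct$a + ct$b + ct$c + ct$d, rep(as.numeric(n_rep), 13))
})

test_that("partition sums hold over random generated report sets", {
  cfg <- sim_config(n_reports = 400, background_event_prob = 0.02,
                    classes = default_vaccine_classes() |>
                      dplyr::mutate(prevalence = pmax(prevalence, 0.02)))
  cm <- sim_class_map()
  for (seed in 1:5) {
    rs <- simulate_reports(cfg, seed = seed)
    n_cases <- sum(is_case(rs, TARGET))
    ct <- contingency_table(rs, TARGET, cm)
    expect_true(all(ct$a + ct$c == n_cases))
    expect_true(all(ct$a + ct$b + ct$c + ct$d == nrow(rs)))
  }
})

test_that("duplicating a drug entry leaves every table unchanged", {
  cm <- toy_class_map()
  rs <- toy_reports()
  dup <- rs
  dup$drugs <- paste(rs$drugs, rs$drugs, sep = ";")
  expect_equal(contingency_table(dup, TARGET, cm),
               contingency_table(rs, TARGET, cm))
})

test_that("adding a suspect drug never decreases that class's a or b", {
  cm <- toy_class_map()
  rs <- toy_reports()
  before <- contingency_table(rs, TARGET, cm, classes = "INFLUENZA")
  grown <- rs
  grown$drugs[2] <- paste0(rs$drugs[2], ";influenza vaccine|suspect||")
  grown$drugs[3] <- paste0(rs$drugs[3], ";influenza vaccine|suspect||")
  after <- contingency_table(grown, TARGET, cm, classes = "INFLUENZA")
  expect_gte(after$a, before$a)
  expect_gte(after$b, before$b)
  expect_equal(after$a, before$a + 1)
  expect_equal(after$b, before$b + 1)
})

test_that("count-based reconstruction validates its feasibility constraints", {
  expect_error(
    contingency_from_counts(tibble::tibble(class_id = "X", a = 80, b = 0),
                            n_cases = 70, n_reports = 1000),
    regexp = "exceeds n_cases"
  )
  expect_error(
    contingency_from_counts(tibble::tibble(class_id = "X", a = 1, b = 990),
                            n_cases = 70, n_reports = 1000),
    regexp = "n_reports - n_cases"
  )
  ok <- contingency_from_counts(tibble::tibble(class_id = "X", a = 5, b = 10),
                                n_cases = 5, n_reports = 100)
  expect_equal(ok$c, 0)
  expect_equal(ok$d, 85)
})
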