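#' Default vaccine class profile for the synthetic database
#'
#' Thirteen vaccine classes with exposure prevalences of the order seen
#' in a worldwide spontaneous-reporting database (per-class share of all
#' reports mentioning the class as suspect, from under 1 in 1,000 for
#' travel vaccines to roughly 1 in 10 for COVID-19), an age profile
#' (paediatric vs adult administration), and a null reporting-rate ratio
#' of 1 for every class.
#'
#' @return Tibble with columns `class_id`, `prevalence`, `rr`,
#'   `age_profile`.
#' @export
default_vaccine_classes <- function() {
  tibble::tibble(
    class_id = c("HPV", "DTP_POLIO", "INFLUENZA", "VARICELLA",
                 "PNEUMOCOCCAL", "HIB", "COVID19", "YELLOW_FEVER",
                 "RABIES", "TYPHOID", "HEP_AB", "HEP_A", "HEP_B"),
    prevalence = c(0.0039, 0.0024, 0.0094, 0.0065, 0.0081, 0.0030,
                   0.0968, 0.0009, 0.0002, 0.0001, 0.0004, 0.0003,
                   0.0021),
    rr = 1,
    age_profile = c("child", "child", "child", "child", "child", "child",
                    "adult", "adult", "adult", "adult", "adult", "adult",
                    "child")
  )
}

#' Configure a synthetic spontaneous-reporting database
#'
#' The generator emulates the statistical structure a case/non-case
#' screen relies on: independent per-class exposure with configurable
#' prevalence, a rare target event whose reporting probability is the
#' background rate multiplied by the largest reporting-rate ratio (`rr`)
#' among the report's exposed classes, and demographic, onset-lag,
#' seriousness and outcome distributions for the descriptive summary.
#' `rr` is a reporting-rate ratio, not a causal effect; setting `rr = 1`
#' everywhere defines the null configuration.
#'
#' Defaults: 13 vaccine classes ([default_vaccine_classes()]); a target
#' event background of 2.35 per million reports (a rare
#' encephalitis-like term); onset lag log-normal with median 4 days and
#' a right tail capped at 730 days; 56% female; 10% missing age, 5%
#' missing country.
#'
#' @param n_reports Number of reports to generate.
#' @param classes Data frame with columns `class_id`, `prevalence`, `rr`
#'   and optionally `age_profile`.
#' @param background_event_prob Probability that an unexposed (or
#'   null-class) report carries the target term.
#' @param target_code,target_name Target event term.
#' @param sex_female_prob Probability of female sex (known-sex reports).
#' @param p_age_missing,p_country_missing Missingness probabilities.
#' @param age_child_median,age_adult_median,age_sdlog Log-normal age
#'   components (years) for paediatric/adult class profiles.
#' @param onset_meanlog,onset_sdlog Log-normal onset lag (days),
#'   default median `exp(log(4)) = 4`.
#' @param onset_cap Upper cap on the onset lag in days.
#' @param country_weights Named sampling weights for reporting country.
#' @param seriousness_probs Named per-criterion probabilities for case
#'   reports (independent draws; empty = non-serious).
#' @param outcome_weights Named sampling weights over outcome levels.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 30000,
                       classes = default_vaccine_classes(),
                       background_event_prob = 2.35e-6,
                       target_code = "LLT_ANMDARE",
                       target_name = "Anti-NMDA receptor encephalitis",
                       sex_female_prob = 0.56,
                       p_age_missing = 0.10,
                       p_country_missing = 0.05,
                       age_child_median = 12,
                       age_adult_median = 30,
                       age_sdlog = 0.5,
                       onset_meanlog = log(4),
                       onset_sdlog = 2,
                       onset_cap = 730,
                       country_weights = c(JP = 0.20, FR = 0.12,
                                           GB = 0.12, US = 0.30,
                                           DE = 0.11, BR = 0.15),
                       seriousness_probs = c(
                         death = 0.03, life_threatening = 0.10,
                         hospitalization = 0.55, disabling = 0.14,
                         congenital_anomaly = 0.0,
                         other_medically_important = 0.18),
                       outcome_weights = c(
                         recovered = 0.20, recovering = 0.11,
                         not_recovered_or_sequelae = 0.45,
                         fatal = 0.035, unknown = 0.205)) {
  cfg <- list(
    n_reports = n_reports,
    classes = tibble::as_tibble(classes),
    background_event_prob = background_event_prob,
    target_code = target_code, target_name = target_name,
    sex_female_prob = sex_female_prob,
    p_age_missing = p_age_missing,
    p_country_missing = p_country_missing,
    age_child_median = age_child_median,
    age_adult_median = age_adult_median,
    age_sdlog = age_sdlog,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    onset_cap = onset_cap,
    country_weights = country_weights,
    seriousness_probs = seriousness_probs,
    outcome_weights = outcome_weights
  )
  class(cfg) <- "sim_config"
  problems <- validate_sim_config(cfg)
  if (length(problems)) {
    abort_param(paste0("invalid sim_config:\n  ",
                       paste(problems, collapse = "\n  ")))
  }
  cfg
}

validate_sim_config <- function(cfg) {
  p <- character()
  if (!is.numeric(cfg$n_reports) || length(cfg$n_reports) != 1 ||
      cfg$n_reports < 0 || cfg$n_reports != round(cfg$n_reports)) {
    p <- c(p, "n_reports must be a non-negative integer")
  }
  cl <- cfg$classes
  if (!all(c("class_id", "prevalence", "rr") %in% names(cl))) {
    p <- c(p, "classes needs columns class_id, prevalence, rr")
  } else {
    if (any(cl$prevalence < 0 | cl$prevalence > 1)) {
      p <- c(p, "class prevalences must be in [0, 1]")
    }
    if (any(cl$rr < 0)) p <- c(p, "class rr must be >= 0")
    if (anyDuplicated(cl$class_id)) p <- c(p, "duplicate class_id")
  }
  probs <- c(cfg$background_event_prob, cfg$sex_female_prob,
             cfg$p_age_missing, cfg$p_country_missing,
             cfg$seriousness_probs)
  if (any(probs < 0 | probs > 1)) {
    p <- c(p, "probabilities must be in [0, 1]")
  }
  if (any(cfg$country_weights < 0) || any(cfg$outcome_weights < 0)) {
    p <- c(p, "sampling weights must be non-negative")
  }
  if (!setequal(names(cfg$outcome_weights), outcome_levels)) {
    p <- c(p, "outcome_weights must cover exactly the outcome levels")
  }
  p
}

#' Class map matching the synthetic generator
#'
#' Maps the generated drug names (`"<class_id> vaccine"`, lowercase) back
#' to their class ids.
#'
#' @param classes Class profile tibble (default the generator's default).
#' @return A [class_map()].
#' @export
sim_class_map <- function(classes = default_vaccine_classes()) {
  class_map(tibble::tibble(
    pattern = paste(tolower(classes$class_id), "vaccine"),
    class_id = classes$class_id,
    match = "exact"
  ))
}

#' Generate a synthetic report line listing
#'
#' Draws `cfg$n_reports` reports: per-class exposures are independent
#' Bernoulli draws at the configured prevalences; the target event is
#' assigned with probability `background_event_prob` times the largest
#' `rr` among the report's exposed classes (1 if unexposed); exposed
#' classes appear as suspect drugs with administration dates; cases
#' carry the target term with an onset date lagged by the configured
#' log-normal; non-cases carry a filler event term. Deterministic given
#' `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param fmt An [icsr_format()] used to pack multi-valued cells.
#' @return An ICSR tibble.
#' @export
simulate_reports <- function(cfg, seed = 1, fmt = icsr_format()) {
  stopifnot(inherits(cfg, "sim_config"))
  problems <- validate_sim_config(cfg)
  if (length(problems)) {
    abort_param(paste0("invalid sim_config:\n  ",
                       paste(problems, collapse = "\n  ")))
  }
  n <- cfg$n_reports
  if (n == 0) {
    return(icsr_reports(character(0), character(0), character(0)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cl <- cfg$classes
  k <- nrow(cl)
  expo <- matrix(FALSE, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    expo[, j] <- rbinom(n, 1, cl$prevalence[j]) == 1
  }
  rr_eff <- rep(1, n)
  for (j in seq_len(k)) {
    if (cl$rr[j] != 1) {
      rr_eff[expo[, j]] <- pmax(rr_eff[expo[, j]], cl$rr[j])
    }
  }
  p_event <- pmin(cfg$background_event_prob * rr_eff, 1)
  case <- rbinom(n, 1, p_event) == 1

  # demographics: age follows the profile of the first exposed class
  profile <- if ("age_profile" %in% names(cl)) cl$age_profile else
    rep("child", k)
  first_class <- apply(expo, 1, function(z) which(z)[1])
  is_adult <- !is.na(first_class) & profile[ifelse(is.na(first_class), 1,
                                                   first_class)] == "adult"
  mix_adult <- is.na(first_class) & runif(n) < 0.5
  adult <- is_adult | mix_adult
  age <- ifelse(adult,
                rlnorm(n, log(cfg$age_adult_median), cfg$age_sdlog),
                rlnorm(n, log(cfg$age_child_median), cfg$age_sdlog))
  age <- pmin(round(age, 1), 120)
  age[runif(n) < cfg$p_age_missing] <- NA_real_

  sex <- ifelse(runif(n) < cfg$sex_female_prob, "female", "male")
  sex[runif(n) < 0.05] <- "unknown"
  country <- sample(names(cfg$country_weights), n, replace = TRUE,
                    prob = cfg$country_weights)
  country[runif(n) < cfg$p_country_missing] <- NA_character_

  admin <- as.Date("2015-01-01") + floor(runif(n, 0, 2556))
  lag <- pmin(floor(rlnorm(n, cfg$onset_meanlog, cfg$onset_sdlog)),
              cfg$onset_cap)
  onset <- admin + lag

  sep_f <- fmt$field_sep; sep_e <- fmt$entry_sep
  drug_cells <- character(n)
  any_expo <- rowSums(expo) > 0
  if (any(any_expo)) {
    idx <- which(any_expo)
    drug_cells[idx] <- vapply(idx, function(i) {
      js <- which(expo[i, ])
      paste(paste0(tolower(cl$class_id[js]), " vaccine", sep_f,
                   "suspect", sep_f, sep_f, admin[i]),
            collapse = sep_e)
    }, character(1))
  }
  filler <- c("paracetamol", "ibuprofen", "amoxicillin", "metformin",
              "atorvastatin")
  drug_cells[!any_expo] <- paste0(
    sample(filler, sum(!any_expo), replace = TRUE), sep_f, "suspect",
    sep_f, sep_f, admin[!any_expo])

  event_cells <- ifelse(
    case,
    paste0(cfg$target_code, sep_f, cfg$target_name, sep_f, onset),
    paste0("LLT_OTHER", sep_f, "Other reaction", sep_f, onset))

  serious <- character(n)
  if (any(case)) {
    # cases in the emulated series are serious; draw one criterion each
    serious[case] <- sample(names(cfg$seriousness_probs), sum(case),
                            replace = TRUE, prob = cfg$seriousness_probs)
  }
  serious[!case & runif(n) < 0.3] <- "other_medically_important"

  outcome <- sample(names(cfg$outcome_weights), n, replace = TRUE,
                    prob = cfg$outcome_weights)

  icsr_reports(
    report_id = sprintf("R%07d", seq_len(n)),
    age_years = age, sex = sex, country = country,
    drugs = drug_cells, events = event_cells,
    seriousness = serious, outcome = outcome
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw per-class screen counts without materialising reports
#'
#' Samples the per-class 2x2 cell counts from exactly the distribution
#' induced by [simulate_reports()]'s event model (independent exposures;
#' event probability = background times the largest rr among exposed
#' classes), using a stratification over the exposure patterns of the
#' non-null classes: pattern occupancies are multinomial, events within
#' a pattern binomial, and null-class exposures are binomial thinnings
#' of the case and non-case totals (exposure is independent of the event
#' for rr = 1 classes). This makes replicated operating-characteristic
#' runs at millions of reports per replicate cheap.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (tibble `class_id`, `a`, `b`), `n_cases`,
#'   `n_reports`.
#' @export
simulate_counts <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- cfg$n_reports
  cl <- cfg$classes
  bg <- cfg$background_event_prob
  sig <- which(cl$rr != 1)
  if (length(sig) > 14) {
    abort_param("counts sampler supports at most 14 non-null classes")
  }

  n_pat <- 2^length(sig)
  pat <- matrix(FALSE, nrow = n_pat, ncol = length(sig))
  if (length(sig)) {
    for (j in seq_along(sig)) {
      pat[, j] <- bitwAnd(seq_len(n_pat) - 1L, bitwShiftL(1L, j - 1L)) > 0
    }
  }
  p_pat <- vapply(seq_len(n_pat), function(i) {
    prod(ifelse(pat[i, ], cl$prevalence[sig], 1 - cl$prevalence[sig]))
  }, numeric(1))
  rr_pat <- vapply(seq_len(n_pat), function(i) {
    if (any(pat[i, ])) max(cl$rr[sig][pat[i, ]], 1) else 1
  }, numeric(1))

  n_by_pat <- as.vector(rmultinom(1, n, p_pat))
  x_by_pat <- rbinom(n_pat, n_by_pat, pmin(bg * rr_pat, 1))
  n_cases <- sum(x_by_pat)

  a <- b <- numeric(nrow(cl))
  for (j in seq_along(sig)) {
    in_pat <- pat[, j]
    a[sig[j]] <- sum(x_by_pat[in_pat])
    b[sig[j]] <- sum(n_by_pat[in_pat]) - a[sig[j]]
  }
  null_idx <- setdiff(seq_len(nrow(cl)), sig)
  for (j in null_idx) {
    a[j] <- rbinom(1, n_cases, cl$prevalence[j])
    b[j] <- rbinom(1, n - n_cases, cl$prevalence[j])
  }
  list(
    counts = tibble::tibble(class_id = cl$class_id, a = a, b = b),
    n_cases = n_cases,
    n_reports = n
  )
}

#' Reconstruct a minimal report set from per-class counts
#'
#' Builds the smallest line listing whose report-level contingency tables
#' reproduce a given count specification exactly: `n_cases` case reports
#' carrying the target term, per-class exposed-case counts packed onto
#' `n_exposed_cases` of them (multi-class case reports absorb
#' specifications whose per-class counts sum past the exposed-case
#' total), `b` single-class exposed non-case reports per class, and
#' unexposed filler for the remainder. With `materialize = FALSE` no
#' rows are built and the contingency table is returned directly — the
#' path used for database-scale count specifications.
#'
#' @param counts Data frame with columns `class_id`, `a`, `b`.
#' @param n_cases,n_reports Totals of the specification.
#' @param n_exposed_cases Number of case reports carrying at least one
#'   exposure; default the smallest feasible packing (`max(a)`, or the
#'   mention total if smaller).
#' @param term A [term_selector()] or term code for the target event.
#' @param materialize Build report rows (`TRUE`) or return the
#'   contingency table directly (`FALSE`).
#' @param fmt An [icsr_format()].
#' @return An ICSR tibble, or a contingency tibble when
#'   `materialize = FALSE`.
#' @export
simulate_tabulated <- function(counts, n_cases, n_reports,
                               n_exposed_cases = NULL,
                               term = term_selector(
                                 code = "LLT_ANMDARE",
                                 name = "Anti-NMDA receptor encephalitis"),
                               materialize = TRUE,
                               fmt = icsr_format()) {
  counts <- tibble::as_tibble(counts)
  term <- as_term_selector(term)
  a <- as.numeric(counts$a); b <- as.numeric(counts$b)
  # shared feasibility checks (also applied on the virtual path)
  ctab <- contingency_from_counts(counts, n_cases, n_reports,
                                  term_code = term_code_of(term))
  if (!materialize) return(ctab)

  total_mentions <- sum(a)
  n_exposed_cases <- n_exposed_cases %||%
    min(n_cases, max(c(a, 0), na.rm = TRUE), total_mentions)
  if (n_exposed_cases > n_cases) {
    abort_param("n_exposed_cases exceeds n_cases")
  }
  if (total_mentions > 0) {
    if (n_exposed_cases < max(a)) {
      abort_param("n_exposed_cases below max per-class a: classes cannot be packed")
    }
    if (n_exposed_cases > total_mentions) {
      abort_param("n_exposed_cases exceeds the total of per-class a")
    }
  }
  if (sum(b) > n_reports - n_cases) {
    abort_param("sum of b exceeds n_reports - n_cases")
  }

  sep_f <- fmt$field_sep; sep_e <- fmt$entry_sep
  admin <- as.Date("2021-01-01")
  onset <- admin + 4

  # pack per-class exposed-case mentions round-robin over the exposed slots
  case_classes <- vector("list", n_cases)
  if (total_mentions > 0 && n_exposed_cases > 0) {
    slots <- rep(seq_len(n_exposed_cases),
                 length.out = total_mentions)
    # ensure early slots get distinct classes: walk classes in order
    pos <- 1L
    ord <- order(-a)
    for (j in ord) {
      if (a[j] == 0) next
      take <- ((pos - 1L + seq_len(a[j]) - 1L) %% n_exposed_cases) + 1L
      for (s in take) {
        case_classes[[s]] <- c(case_classes[[s]], counts$class_id[j])
      }
      pos <- pos + a[j]
    }
  }
  drug_of <- function(cls) {
    paste(paste0(tolower(cls), " vaccine", sep_f, "suspect", sep_f, cls,
                 sep_f, admin), collapse = sep_e)
  }
  case_drugs <- vapply(case_classes, function(cls) {
    if (length(cls)) drug_of(cls) else
      paste0("paracetamol", sep_f, "suspect", sep_f, sep_f, admin)
  }, character(1))
  target_cell <- paste0(term$code %||% "LLT_TARGET", sep_f,
                        term$name %||% "", sep_f, onset)
  other_cell <- paste0("LLT_OTHER", sep_f, "Other reaction", sep_f, onset)

  noncase_class <- rep(counts$class_id, b)
  n_filler <- n_reports - n_cases - length(noncase_class)
  rs <- icsr_reports(
    report_id = sprintf("S%08d", seq_len(n_reports)),
    drugs = c(case_drugs,
              vapply(noncase_class, drug_of, character(1),
                     USE.NAMES = FALSE),
              rep(paste0("paracetamol", sep_f, "suspect", sep_f, sep_f,
                         admin), n_filler)),
    events = c(rep(target_cell, n_cases),
               rep(other_cell, n_reports - n_cases)),
    seriousness = c(rep("hospitalization", n_cases),
                    rep("", n_reports - n_cases)),
    outcome = "unknown"
  )
  rs
}

#' Reference evaluation designs for the screen
#'
#' Two fixed simulation designs used to characterise the screen:
#'
#' `null_screen_config()` — the null calibration design: 10 classes at
#' exposure prevalence 0.1, all reporting-rate ratios 1, one million
#' reports, event background 5 per 10,000. Expected cell counts
#' (`a` about 50, `c` about 450) sit in the asymptotic regime of the
#' Woolf interval, so the two-sided rejection rate of a null class
#' estimates the nominal type-I error; at small expected `a` (around 10
#' and below) the interval is conservative and rejects less often than
#' nominal.
#'
#' `power_screen_config()` — the power design: one class with reporting
#' rate ratio 10 at exposure prevalence 0.004 against nine null classes
#' at prevalence 0.01, two million reports, event background 2.4 per
#' 10,000, giving an expected exposed-case count near 19 for the signal
#' class.
#'
#' @return A [sim_config()].
#' @export
null_screen_config <- function() {
  sim_config(
    n_reports = 1e6,
    background_event_prob = 5e-4,
    classes = tibble::tibble(
      class_id = paste0("NULL", sprintf("%02d", 1:10)),
      prevalence = 0.1, rr = 1
    )
  )
}

#' @rdname null_screen_config
#' @export
power_screen_config <- function() {
  sim_config(
    n_reports = 2e6,
    background_event_prob = 2.4e-4,
    classes = tibble::tibble(
      class_id = c("SIGNAL", paste0("NULL", sprintf("%02d", 1:9))),
      prevalence = c(0.004, rep(0.01, 9)),
      rr = c(10, rep(1, 9))
    )
  )
}
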