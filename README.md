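# rorscreen

Case/non-case disproportionality screening for spontaneous adverse-event
reports, with a synthetic reporting-database generator for end-to-end
testing and operating-characteristic evaluation.

## The problem

Pharmacovigilance databases hold millions of individual case safety
reports (ICSRs) but no denominator of exposed persons, so absolute risks
cannot be estimated from them. Signal detection instead asks whether an
adverse event is reported *disproportionately* often with a drug class.
In the case/non-case design, reports coded with the event term of
interest are the cases and every other report is a non-case; for each
drug class a 2×2 table of report counts is built (a = exposed cases,
b = exposed non-cases, c = unexposed cases, d = unexposed non-cases) and
the reporting odds ratio

    ROR = a·d / (b·c)

is computed with a Woolf (log-normal) 95% confidence interval,
exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)), and a Pearson chi-square
p-value (1 d.f., no continuity correction). Classes with fewer than
three exposed cases are not evaluable; an evaluable class whose lower
confidence bound exceeds 1 is flagged as a pharmacovigilance signal —
disproportionate reporting that warrants pharmacological assessment, not
evidence of causation.

The package is aimed at pharmacovigilance analysts and methodologists:
it takes tidy data frames in and returns tibbles, so screens compose
with the usual dplyr/ggplot2 workflow, and fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

The package ships the per-class screening counts for anti-NMDA receptor
encephalitis — a rare autoimmune encephalitis — across vaccine classes
in a worldwide spontaneous-reporting database: 70 case reports among
29,758,737 reports. The counts path rebuilds each class's 2×2 table from
(a, b) and the totals without materialising any report rows:

```r
library(rorscreen)

counts <- anmdare_vaccine_counts()
ctab <- contingency_from_counts(counts, attr(counts, "n_cases"),
                                attr(counts, "n_reports"),
                                term_code = "LLT_ANMDARE")
label_map <- class_map(
  tibble::tibble(pattern = tolower(counts$label), class_id = counts$class_id),
  labels = tibble::tibble(class_id = counts$class_id, label = counts$label))
screen_counts(ctab, labels = label_map)
```

```
Case/non-case disproportionality screen
  term: LLT_ANMDARE   reports: 29,758,737   cases: 70
  filter: a >= 3   CI level: 0.95
# A tibble: 13 × 7
   class                        a       b ROR     `95% CI`       p        status
   <chr>                    <dbl>   <dbl> <chr>   <chr>          <chr>    <chr>
 1 DTP-polio vaccine            8   70006 "54.72" "[26.2-114]"   "<0.001" signal
 2 Yellow fever vaccine         3   26614 "50.02" "[15.7-159]"   "<0.001" signal
 3 HPV vaccine                  8  116283 "32.89" "[15.8-68.7]"  "<0.001" signal
 4 HIB vaccine                  4   89544 "20.08" "[7.32-55.1]"  "<0.001" signal
 5 Varicella zoster vaccine     5  193141 "11.78" "[4.74-29.2]"  "<0.001" signal
 6 Influenza vaccine            7  280525 "11.68" "[5.35-25.5]"  "<0.001" signal
 7 Pneumococcal vaccine         4  241627 "7.4"   "[2.7-20.3]"   "<0.001" signal
 8 COVID-19 vaccine             4 2881218 "0.57"  "[0.206-1.55]" "0.262"  no_si…
 9 Rabies vaccine               2    6474 ""      ""             ""       not_e…
...
No multiple-testing adjustment applied.
```

Reading the output: eight classes have at least three exposed cases and
are evaluable; seven of them have a lower confidence bound above 1 and
are signals. The COVID-19 class reports an ROR of 0.57 with an interval
spanning 1 (p = 0.262): its four exposed cases are *fewer* than its huge
exposure share of the database would predict, so no disproportionality.
The five classes below the filter keep their counts but carry no
statistics. `tidy()` on the same object returns the full-precision
columns, and `autoplot()` draws the forest plot.

The rest of the toolkit: `read_icsr()`/`write_icsr()` for delimited line
listings with packed drug/event cells, `screen_signals()` for the
end-to-end screen on a listing, `summarize_cases()`/`age_by_class()` for
the descriptive case series, `simulate_reports()` /
`simulate_counts()` / `simulate_tabulated()` for synthetic databases and
count reconstructions, `evaluate_oc()` for type-I error and power, and
`run_screen()`/`run_describe()`/`run_simulate()` (plus the thin
`inst/cli/pvscreen.R` wrapper) for scripted runs with manifests. The
methods vignette (`vignettes/disproportionality-screening.Rmd`) explains
the model, the generator and every numerical choice.

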