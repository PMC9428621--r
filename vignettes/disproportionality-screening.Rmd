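---
title: "Case/non-case disproportionality screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The design

Spontaneous-reporting databases collect individual case safety reports
(ICSRs): one report per patient, each listing suspect and concomitant
drugs, coded adverse-event terms, demographics, seriousness and outcome.
Because there is no denominator of exposed persons, absolute risks cannot
be estimated from such data. The case/non-case design works around this
by comparing *reporting odds*: reports coded with the event term of
interest are the cases, every other report in the database over the same
period is a non-case, and for each drug class a 2×2 table is formed at
the report level:

|              | case | non-case |
|--------------|------|----------|
| exposed      | a    | b        |
| not exposed  | c    | d        |

Exposure means the class appears among the report's *suspect* drugs
(concomitants are excluded by default and can be included with a flag).
Counting is per report: a report with two suspect drugs of the same class
contributes once to that class, and a multi-class report contributes to
several classes. The comparator is the whole database: `c` includes case
reports exposed to *other* classes, so each class's four cells always sum
to the total report count.

The reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},$$

with the Woolf (log-normal) confidence interval

$$\exp\!\left(\ln \mathrm{ROR} \pm z_{1-\alpha/2}
  \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

and a Pearson chi-square test (1 d.f., no continuity correction) for the
association p-value. A class is *evaluable* only if it has at least
`min_exposed_cases` exposed cases (default 3, the conventional
minimum-count filter), and an evaluable class is flagged as a *signal*
when the lower confidence bound exceeds 1 — equivalent to a two-sided
Wald test on the log ROR at the same level. The Pearson p-value is
reported alongside; for extreme tables the two can differ slightly in
the third decimal. A ROR is a measure of disproportionate *reporting*,
never of causal risk, and no multiple-testing adjustment is applied
(the output says so in its metadata).

## Parameters that matter

* `min_exposed_cases` (count, default 3) — the evaluability filter.
  Below it, cell `a` is so small that the asymptotic interval is
  meaningless; rows keep their counts but carry no statistics.
* `level` (default 0.95) — confidence level of the Woolf interval and
  the implied test level.
* `zero_cell` (default `"error"`) — zero cells make the ratio or its
  variance undefined. The default refuses loudly; `"haldane"` adds 0.5
  to every cell of the affected table; `"na"` returns missing statistics
  and is what batch screens use internally. With the default filter a
  zero `a` cannot reach the statistics; a zero `b` can occur in tiny
  synthetic databases.
* Display rounding (print method and display writer): ROR to 2 decimal
  places, interval bounds to 3 significant figures, p-values to 3
  decimals with values below 0.0005 shown as `<0.001`.

## The worked example

The package ships `anmdare_vaccine_counts()`: per-vaccine-class counts
for anti-NMDA receptor encephalitis (a rare autoimmune encephalitis,
about 1.5 cases per million persons per year, predominantly in women and
the young) in a worldwide spontaneous-reporting database of 29,758,737
reports with 70 case reports. The counts path rebuilds each 2×2 table
from `a`, `b` and the totals (`c = 70 - a`, `d = N - 70 - b`) without
materialising rows:

```{r example}
counts <- anmdare_vaccine_counts()
ctab <- contingency_from_counts(counts, attr(counts, "n_cases"),
                                attr(counts, "n_reports"),
                                term_code = "LLT_ANMDARE")
screen_counts(ctab)
```

Eight classes pass the filter; seven are signals, and the COVID-19 class
(ROR 0.57, interval spanning 1, p = 0.262) is the lone evaluable
no-signal. Five classes with fewer than three exposed cases are not
evaluable. For those five, only presence below the filter is published;
their `a` values here are a synthetic completion consistent with the
published totals and their `b` values are placeholders (see the help
page) — they never enter any statistic.

## The synthetic database generator

Real ICSR databases are access-restricted, so every stage of the
pipeline is testable against a generator that emulates the structure the
analysis relies on:

* per-class exposure: independent Bernoulli draws at configurable
  prevalences (defaults span roughly 1/10,000 for travel vaccines to
  1/10 for COVID-19, the orders of magnitude seen in a worldwide
  database);
* the target event: background reporting probability (default 2.35 per
  million reports, a rare encephalitis-like term) multiplied by the
  largest reporting-rate ratio `rr` among the report's exposed classes.
  This multiplicative model is the simplest mechanism whose induced ROR
  approximates `rr` when the event is rare; `rr` is a reporting-rate
  ratio, not a causal effect, mirroring the design's own limitation;
* demographics and dates: a two-component (paediatric/adult) log-normal
  age model keyed to each class's administration profile, configurable
  sex, country and missingness rates, and a log-normal onset lag with
  median 4 days capped at 730 days — the time-to-onset scale reported
  for post-vaccination encephalitis case series;
* seriousness and outcome category weights for the descriptive summary.

What the generator does **not** emulate: duplicate and follow-up
reports, reporting-culture differences between countries, dependence of
reporting probability on seriousness, partial dates, and real drug-name
vocabularies. Passing tests therefore demonstrate the statistical
machinery, not robustness to those real-data artefacts.

Two sampling paths produce identical distributions of the screen's
inputs. `simulate_reports()` materialises every report row and exercises
the full pipeline (reading, term matching, class mapping, counting).
`simulate_counts()` draws the per-class 2×2 cells directly: exposure
patterns over the non-null classes are multinomial, events within a
pattern binomial, and null-class exposures binomial thinnings of the
case and non-case totals (exposure is independent of the event when
`rr = 1`). The count path makes replicated evaluations at millions of
reports per replicate cheap; the test suite checks the two paths agree
on moderate sizes.

`simulate_tabulated()` inverts the counting: given per-class `a`, `b`
and totals it builds a minimal line listing whose contingency tables
reproduce those counts exactly, packing multi-class case reports when
the per-class counts sum past the exposed-case total. With
`materialize = FALSE` it skips row construction entirely and returns the
contingency table — the path used for database-scale specifications.

## Operating characteristics

`evaluate_oc()` replicates generate-and-screen runs (replicate *i* uses
seed `seed + i`) and reports two null error rates: the **two-sided
rejection rate** (interval excludes 1), whose nominal level is
`1 - level`, and the **directional signal rate** (lower bound above 1),
which runs at about half that under the null. Power for a non-null class
is the probability of a signal flag, counting replicates where the class
fails the filter as misses.

Two packaged reference designs fix the evaluation conditions:

* `null_screen_config()` — 10 null classes at prevalence 0.1, one
  million reports, background 5 per 10,000, so the expected exposed-case
  cell is about 50 and the interval operates in its asymptotic regime.
  At small expected counts (`a` around 10 and below) the Woolf interval
  is conservative — measured two-sided rejection near 0.034 rather than
  0.05 — which is a property of the interval worth knowing when
  screening rare events, and the reason the calibration design uses
  larger cells.
* `power_screen_config()` — one class with `rr = 10` at prevalence
  0.004 among nine null classes, two million reports, background 2.4 per
  10,000. The expected signal cell is `a ≈ 19.2` with `c ≈ 478`,
  giving an expected log-ROR of `ln 10` against a standard error near
  0.23, so detection is essentially certain and the 90% power bound in
  the acceptance suite has a wide margin. (With a rare-disease
  background of a few per million at this scale the expected `a` would
  be below 1 and no design could pass the filter; the background is
  therefore set to the value that realises the intended cell counts at
  this rate ratio, prevalence and database size.)

The test suite runs 500 null replicates and 200 power replicates through
the count path (seconds each); the row-level path is exercised at
smaller sizes.

## Numerical and design choices

* **Interval and test choice.** The Woolf interval and the uncorrected
  Pearson chi-square jointly reproduce the worked example's published
  statistics, including the one p-value large enough to discriminate
  between candidate tests (a Wald log-OR test gives 0.268 where the
  Pearson test gives the published 0.262); a Yates-corrected test is
  not used anywhere.
* **Cells as doubles.** Counts are validated as non-negative integers
  and then held as doubles: the Pearson numerator multiplies four
  margins of a 29.7-million-row table and overflows 32-bit integers.
* **Medians** use the even-*n* midpoint convention throughout, so
  half-integer medians (36.5 years) are representable.
* **Age strata** are [0, 15) and [15, 30], with the boundary assigned
  upward; every percentage in the case summary carries its known-value
  denominator, and unknown age/sex/country values are never imputed.
* **Two counting conventions coexist and are labelled.** Contingency
  cells are report-level (a report counts once per class); descriptive
  drug-class shares are mention-level (each suspect drug entry counts),
  matching how case series report "x% of suspect drugs".
* **Time to onset** is the earliest matching event onset minus the
  latest administration of a suspect drug of the class on or before
  that onset, in whole days; chronologically impossible pairs (all
  administrations after onset) become missing with a warning rather
  than negative lags.
* **Line-listing format.** One row per report with drugs/events packed
  into sub-delimited cells, UTF-8, ISO-8601 dates, configurable
  delimiters. Packed flat files diff cleanly and round-trip exactly;
  partial dates are out of scope.
* **Determinism.** Every stochastic entry point takes a seed; the
  generator saves and restores the global RNG state, identical
  (config, seed) pairs write byte-identical listings, and the pipeline
  writes no timestamps into result files, so a run manifest plus inputs
  fully determines all outputs.

## Problem sizes in the checks

The acceptance suite reproduces the full-scale worked example through
the counts path (no 29.7-million-row materialisation), brute-force
tallies a 1/1000-scaled materialised reconstruction (29,759 rows), runs
1,000 random tables against independent direct-formula oracles, 500
null replicates and 200 power replicates through the count sampler, and
a rate-ratio recovery grid at 400,000 reports per point. These sizes
were chosen so the whole suite runs in about a minute while every
statistical claim still has the replicate counts quoted above.

## Known limitations

Exact term matching only (no dictionary hierarchy roll-up);
no deduplication of follow-up reports; no stratified or adjusted
tables; no PRR/EBGM/Bayesian information-component statistics; the
case/non-case design itself cannot support causal inference, and the
no-multiplicity choice mirrors common screening practice rather than a
recommendation.
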