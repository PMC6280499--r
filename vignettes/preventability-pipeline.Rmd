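---
title: "Assessing adverse drug event preventability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing adverse drug event preventability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adeprev)
```

## The problem

Adverse drug events (ADEs) — harm from the use or misuse of a medication —
are a leading cause of emergency department visits and unplanned
admissions. Whether a given event *could have been avoided* is the question
every prevention programme turns on, yet preventability is a judgment, and
studies using different judgment instruments report preventable fractions
anywhere from roughly a quarter to four fifths of events. Comparing
instruments requires applying several of them to the same events, by more
than one clinician, and quantifying agreement.

`adeprev` implements the quantitative side of such a comparison study. A
cohort of ADEs is rated independently by two clinicians (a pharmacist and a
physician), each using three instruments:

* a **best-practice** definition (was the event avoidable by adherence to
  best medical practice?) — a global clinical judgment;
* an **error-based** definition (did a medication error or unaddressed
  modifiable risk factor contribute?) — also a judgment;
* an **algorithm**: a modified Schumock–Thornton questionnaire of 18
  explicit Yes/No/Uncertain criteria.

Every rating is on the ordered scale
`NOT_PREVENTABLE < PROBABLY < DEFINITELY`. Discordant rater pairs are
discussed to consensus; a third reviewer adjudicates what discussion cannot
settle. The package computes consensus proportions with confidence
intervals, chance-corrected inter-rater and between-method agreement, and
the frequency with which each algorithm criterion drove a preventable
rating.

The two definition-based instruments are human judgments: their ratings
enter the pipeline as data and are never automated here. Only the
algorithm instrument is executable.

## The rule engine

The modified algorithm partitions its criteria into **definite triggers**
(an affirmative answer forces "definitely preventable") and **probable
triggers** (forcing "probably preventable"):

```{r}
criterion_severity_map()[, c("criterion_id", "severity", "gate")]
```

Two questions are pure gates: Q1 (history of allergy or prior reaction)
opens the nested follow-up Q1a (was the re-exposure inappropriate?), and
Q9 (preventative measures not prescribed?) opens Q9a (were they not
contraindicated?). A follow-up can only fire when its gate is answered
YES; its recorded response is ignored otherwise.

Classification is then a maximum over fired severities:

* any definite trigger fires → `DEFINITELY`;
* else any probable trigger fires → `PROBABLY`;
* else `NOT_PREVENTABLE`.

```{r}
resp <- setNames(rep("NO", 20), criterion_severity_map()$criterion_id)
resp["7"] <- "YES"                 # drug interaction: probable trigger
classify_form(resp)
resp["4"] <- "YES"                 # toxic drug level: definite trigger wins
classify_form(resp)
```

**UNCERTAIN handling.** The instrument's footnotes attach consequences
only to "Yes" answers, and nothing in the workflow suggests uncertainty
escalates a rating. We therefore treat UNCERTAIN as non-affirmative: it
never fires a trigger, and replacing UNCERTAIN by NO never changes a
classification. This is the conservative reading; the test suite pins it
as an invariant.

**Input dialects.** Collection forms in the field phrase Q1a with either
polarity ("was the re-exposure appropriate?" vs "inappropriate?") and
sometimes expand Q5 into a three-part chain (known treatment exists / was
not prescribed / was not contraindicated). The engine is canonical —
Q1a is the *inappropriateness* question, Q5 is flat — and `read_forms()`
normalises both dialects at the boundary with a logged message, so the
rule set exists exactly once.

## Consensus workflow

`resolve_consensus()` and `consensus_dataset()` reproduce the review
procedure: concordant pairs stand; discordant pairs take the recorded
discussion outcome; adjudication is consulted only when discussion is
absent. Discussion and adjudication outcomes are **inputs** (a
resolutions table). The study's consensus is a human conversation;
synthesising it from the two ratings would misrepresent the method, so a
discordant pair with no recorded outcome is an error, not a guess. The
discussion outcome is not constrained to equal either original rating —
reviewers sometimes settle on the middle category.

## Agreement statistics

For two raters over `k` categories with contingency table `N` (total
`n`), the package computes Cohen's kappa

\[
\kappa = \frac{p_o - p_e}{1 - p_e}, \qquad
p_o = \frac{\sum_i N_{ii}}{n}, \qquad
p_e = \frac{\sum_i N_{i\cdot} N_{\cdot i}}{n^2},
\]

with the asymptotic standard error
\(\mathrm{SE} = \sqrt{p_o (1 - p_o) / (n (1 - p_e)^2)}\) and the normal
interval \(\kappa \pm z_{\alpha/2}\,\mathrm{SE}\), truncated to
\([-1, 1]\). The z quantile comes from `qnorm()` at the configured
confidence, never a hard-coded 1.96. If both raters use one identical
category, \(p_e = p_o = 1\) and kappa is defined as 1 with a zero-width
interval.

Proportions are reported as percents with a **Wald** interval
\(\hat p \pm z \sqrt{\hat p(1-\hat p)/n}\) by default — chosen because it
reproduces the confidence bounds printed in the chart-review literature
this package mirrors, cell for cell, from the raw counts. The Wilson
score interval (`method = "wilson"`, via `prop.test(correct = FALSE)`) is
available where its better small-sample behaviour matters. All percents
are rounded **half up** to one decimal and kappas to two; `round()`'s
half-to-even rule disagrees on exactly the tie cases percent tables
produce.

Three cohort-level wrappers assemble the published comparisons:

* `interrater_agreement(..., scale = "binary")` — pharmacist vs physician
  after collapsing `DEFINITELY + PROBABLY` into `PREVENTABLE`;
* `interrater_agreement(..., scale = "definitely_vs_probably")` — a 2×2
  kappa on the preventable subset. The default subset
  (`consensus_preventable`) is events whose *consensus* rating under the
  method is preventable, which matches how the published subset sizes
  line up with the consensus preventable counts; `rater_preventable`
  (both raters rated preventable) is exposed as the alternative reading.
  Events in the subset where one rater nonetheless said "not preventable"
  cannot be placed on the two-level scale and are dropped with a message.
* `intermethod_agreement()` — binary kappa between two methods' consensus
  ratings over their common events.

## Criterion attribution

`attribute_forms()` lists every fired trigger per event;
`criterion_frequency()` turns the pharmacist's attributions into a
frequency table. Two denominators are exposed because the natural one is
genuinely ambiguous: `all_events` (the whole cohort) and
`definite_trigger_events` (only events with at least one definite
trigger — the events whose rating the instrument forces to "definitely"
with no option to soften it). The pipeline's default is the latter,
matching the framing in which such tables are usually printed; pass
`denominator_policy = "all_events"` for the cohort-wide proportion.

## The synthetic cohort generator

No chart-review data ship with the package; `simulate_cohort()` generates
datasets with the statistical structure the analysis assumes:

1. each event draws one **latent category** from `prevalence`
   (default `NOT .359, PROBABLY .577, DEFINITELY .064`, the consensus
   marginals of a large emergency-department cohort under a
   best-practice definition);
2. a per-method 3×3 **method confusion** matrix maps the latent category
   to the event's method-level truth. Defaults: identity for best
   practice; nearly identity for the error-based definition (binary
   agreement ≈ 0.99); for the algorithm, probable events are promoted to
   definite with probability 0.64 and some non-preventable events are
   netted in — explicit single-criterion instruments over-call
   "definitely", and this matrix reproduces that regime (~45% definite,
   ~67% preventable, binary between-method agreement ≈ 0.88);
3. each rater observes the method truth through a 3×3 **rater confusion**
   matrix, independently given the truth. The default rows give binary
   sensitivity 0.90 and specificity 0.85 for both roles, which puts the
   expected binary inter-rater kappa at ≈ 0.55–0.56 — the mid-0.5 regime
   reported for dual-clinician chart review;
4. algorithm **forms** are built consistent with each rater's algorithm
   rating: one trigger of matching severity (definite triggers drawn
   with weights echoing observed attribution frequencies — re-exposure
   and toxic-level criteria dominate; probable triggers uniform, as no
   frequency data exist for them), its gate set, all other cells NO or —
   with probability `uncertain_rate = 0.05` — UNCERTAIN, which cannot
   fire;
5. **resolutions** for every discordant pair: the outcome is the event's
   method-level truth, recorded as a discussion with probability 0.9 and
   as an adjudication otherwise (`adjudication_prob = 0.1`; published
   studies rarely state this split, so it is a package choice).

Draws follow a fixed, documented order under one `set.seed()`, so a seed
reproduces a cohort byte for byte across runs and releases.

`expected_binary_kappa()` computes the exact expected binary inter-rater
kappa by enumerating the latent × truth × observed-pair probability
table in closed form. It is the analytic oracle for parameter-recovery
tests: at the study size (1356 events) the empirical kappa falls within
±3 asymptotic SEs of the analytic value in well over 95% of seeded
replicates.

```{r}
cfg <- simulation_config(n_events = 200, seed = 7)
expected_binary_kappa(cfg, "BEST_PRACTICE")
cohort <- simulate_cohort(cfg)
interrater_agreement(cohort$assessments, "BEST_PRACTICE", "binary")
```

**What the generator does not emulate.** Rater errors are conditionally
independent given the latent category; real reviewers share charts,
training and hindsight, so their errors are positively correlated and
real kappas can differ from the independence value at matched accuracy.
There is no event-level difficulty, no drift over the review period, no
association between criterion pattern and rater error, and the two
definition-based methods are simulated at the rating level only. Passing
tests therefore demonstrate that the *pipeline* is correct under the
stated model, not that the model captures every feature of chart-review
data.

## The full pipeline

```{r}
report <- run_study(simulate_cohort(simulation_config(n_events = 150,
                                                      seed = 11)))
report$interrater_binary[, c("method", "n", "formatted")]
```

`run_study()` also cross-checks every supplied form against its rater's
recorded algorithm rating (`log$algorithm_form_mismatches` — a
data-entry signal in file mode, and identically zero for generated
cohorts), and `write_report()` emits deterministic CSVs plus a
full-precision `summary.json` from which
`report_tables_from_summary()` can regenerate every formatted table.

## Numerical and design notes

* **Problem sizes.** The shipped tests exercise the engine exhaustively
  over a 7-criterion reduced form (3^7 = 2187 cases), properties on
  10,000 random forms, the kappa oracle on 1,000 random tables, and
  parameter recovery over 200 replicates at 1356 events — sizes chosen
  so the whole suite runs in well under a minute on one core.
* **Known source inconsistencies.** Two published percent cells this
  package's formatting was checked against disagree with their own
  printed counts by 0.1 (a double-rounding slip: 873/1356 = 64.38 → 64.4
  printed as 64.3, and 28.346% printed as 28.4). The package reports the
  arithmetically correct values; the test suite documents both.
* **Ties and rounding.** Round-half-up is applied only at the formatting
  boundary; every table carries full-precision values alongside the
  formatted string.
* **Degenerate inputs.** Empty contingency tables, `n = 0` proportions,
  discordant pairs without a resolution, events missing one rater, and
  empty definitely-vs-probably subsets are all hard errors that name the
  offending events — silent repair would hide exactly the data problems
  a chart-review pipeline exists to surface.
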