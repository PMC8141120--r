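---
title: "A three-state Markov cost-utility model for psychotropic deprescribing in institutionalized dementia patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov cost-utility model for psychotropic deprescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demcua)
```

## The question and the model

A structured, consensus-based medication review in nursing homes reduces
inappropriate psychotropic prescriptions in dementia patients. Withdrawal of
neuroleptics has been shown in trial data to improve survival; the review
also lowers drug spending. Is the review worth paying for, compared with
standard care, from a healthcare-system perspective?

`demcua` answers this with a deterministic Markov cohort model over three
mutually exclusive health states — *baseline health* (no dementia),
*deteriorated health* (dementia) and *dead* — advanced in annual cycles.
Each alive state carries an annual healthcare cost and a utility weight;
accumulating occupancy-weighted utilities yields QALYs and
occupancy-weighted costs yields total cost per arm. The comparison of the
two arms (standard care vs. medication review) is summarized as incremental
cost $\Delta C$, incremental effect $\Delta E$ (QALYs), the ICER
$\Delta C / \Delta E$ classified on the cost-effectiveness plane, and the
net monetary benefit $\mathrm{NMB} = \lambda \Delta E - \Delta C$ at
willingness-to-pay $\lambda$.

Four transition probabilities drive the cohort: incidence
(baseline → deteriorated), recovery (deteriorated → baseline, fixed at 0
here: dementia is not reversible), and mortality out of each alive state.
Mortality is an age-dependent all-cause schedule $q_x$ multiplied by a
per-state relative risk, capped at 1. The baseline state has RR 1 (it *is*
the reference population); the deteriorated state has RR > 1, i.e. excess
mortality on top of the schedule.

## Parameters and their derivation

All base-case inputs are assembled by `build_paper_arms()` from their raw
observed inputs rather than hard-coded:

```{r arms}
arms <- build_paper_arms()
str(arms$intervention)
```

* **Mortality RRs.** A neuroleptic-withdrawal trial reports cumulative
  survival at 12/24/36 months: 70/46/30% under continued neuroleptics,
  77/71/59% after withdrawal. `mortality_rate_from_survival()` takes one
  minus the arithmetic mean of each triple (0.513 and 0.310);
  `rr_from_excess_mortality()` rounds the excess to two decimals and adds 1,
  giving RR 1.51 (control) and 1.31 (intervention). The additive-excess
  reading is used because it exactly reproduces the published parameter
  chain 0.513 → 0.51 → 1.51; an unrounded variant
  (`round_digits = NULL`) is available for sensitivity work. Since
  excess $= (\mathrm{RR}-1)\,q_x$, this is equivalent to multiplying the
  life-table probability by the RR.
* **Costs.** Only drug-related costs differ between arms: 2265.68
  EUR/patient/year before the review, and afterwards the mean of the 1- and
  6-month follow-up observations, `post_intervention_state_cost(c(1720.77,
  1539.90))` = 1630.335 (computation keeps the unrounded value; 1630 is a
  display rendering). The review itself costs 30 minutes of staff time per
  patient; the hourly rate is not directly observed, so it is a
  configuration input with 97.12 EUR/h documented as the value implied by
  48.56 EUR per half hour. Baseline-state costs are 0 because the review
  only targets patients who already have dementia; the one-off cost is 0
  (the therapeutic guideline itself is free at point of use).
* **Utilities.** 0.70 (baseline), 0.27 (deteriorated), 0 (dead), identical
  across arms: the intervention acts on mortality, not on health-related
  quality of life within a state.
* **Transitions.** Incidence 0.40 per cycle in both arms — the dementia
  prevalence among institutionalized patients in the study area, adopted as
  the per-cycle (annual) transition input; recovery 0.

The configured cohort: target ages 65–90, 75% women, cohort mean age 87,
willingness to pay 15,000 EUR/QALY, population 200 for cumulative runs.
The packaged YAML (`system.file("extdata", "paper_base_case.yaml", package
= "demcua")`) mirrors these values and round-trips through
`read_model_config()` / `write_model_config()`.

## The drug-cost (boxes) algorithm

Per prescription line, the annual cost is whole dispensed boxes times box
price: `ceil(units_per_administration × administrations_per_day ×
min(treatment_days, 365) / units_per_box)`. Two choices deserve note.
Treatment lengths beyond a year are capped at 365 days, so a 500-day course
costs exactly as much as a one-year course. And box counts round *up*: the
source material says "number of boxes" without a rounding rule, and you
cannot dispense a fraction of a box. The synthetic plan generator
(`generate_synthetic_plans()`) draws per-patient drug counts from a Poisson
with mean 8.04 (the observed pre-review mean number of drugs per patient)
and doses, frequencies, pack sizes (14–60 units), prices (2–60 EUR) and
treatment lengths (30–540 days, deliberately straddling the cap) from
ranges typical of psychotropic and co-medication prescribing. These
distributions are the package's own choices; only the count mean is an
observed quantity.

## The life table

The reference mortality schedule is a synthetic Gompertz–Makeham law,
$q_x = 1 - \exp\{-(c + a e^{bx})\}$, capped at 1
(`generate_gompertz_life_table()`, defaults $a = 2.7\times10^{-5}$,
$b = 0.095$, $c = 0$). The defaults give roughly 1.3% annual mortality at
65 rising to 13% at 90 — the shape, not the exact values, of a
Southern-European old-age schedule. The headline result (dominance at every
age) is a *property of the parameter set*, not of any particular national
table: it holds for any schedule that increases with age, which the test
suite exercises with several parameterizations. Real period-vs-cohort
life-table distinctions, calendar years and HMD formats are out of scope;
users can supply any CSV with columns `age,sex,qx`.

## Numerical and design choices

* **Within-cycle ordering.** Death is resolved first; incidence and
  recovery apply among survivors. An incidence of 0.40 therefore means 40%
  of a cycle's *survivors* of the baseline state deteriorate. Other
  orderings are defensible; this one keeps the incidence input
  interpretable as a conditional-on-survival probability.
* **Cycle valuation.** State membership is valued at end of cycle
  (contributions for cycles $t \ge 1$, discounted by $(1+r)^{t-1}$). A
  half-cycle-correction switch (`half_cycle_correction = TRUE`) values the
  average of start- and end-of-cycle occupancy instead; it is off by
  default. With the 12-month base case (one cycle) the choice only scales
  both arms identically, so the dominance classification is unaffected.
* **Discounting.** Defaults to 0 for both costs and effects: the base-case
  horizon is 12 months, where discounting is immaterial. Both rates are
  configurable for the 40-year population runs.
* **Recurrent cost scope.** The review's recurrent cost (48.56
  EUR/patient/year) is charged to every *alive* patient in the intervention
  arm by default; `recurrent_cost_scope = "deteriorated"` restricts it, and
  with the base case's 100%-deteriorated, zero-recovery cohort the two
  choices coincide.
* **Initial state.** 100% deteriorated, because the review targets patients
  who already have dementia. A mixed start reproduces two-alive-state flow
  curves.
* **Sex.** Female and male cohorts are simulated separately and their
  outcomes mixed 75/25 — with a single-schedule life table the two coincide,
  but sex-specific tables are supported.
* **Aggregation over ages.** Per-age results use a fresh cohort at each
  starting age. The pooled ICER dot is taken at the unweighted mean
  $\Delta C, \Delta E$ across ages 65–90, since no empirical age
  distribution for the aggregate is available.
* **Degenerate ICERs.** $\Delta E = 0$ with $\Delta C \ne 0$ yields class
  `ratio` with an undefined ICER value and acceptance decided by the sign
  of $\Delta C$; the exact origin $(0, 0)$ is classed `equivalent`,
  accepted by convention and flagged. Neither occurs in the base case.

## What the analysis shows

With the base-case parameters and any age-increasing life table, at every
starting age 65–90 the intervention arm has lower total cost (the
post-review drug cost plus review fee, 1678.9 EUR per surviving
deteriorated patient-year, is well below the 2265.68 EUR pre-review cost)
and higher QALYs (more survivors, RR 1.31 < 1.51, at equal utilities) — the
intervention is *dominant* and accepted at any non-negative willingness to
pay. Savings per patient shrink with age (background mortality compresses
both arms' survivorship) while QALY gains grow over a one-year horizon
(the RR gap matters more when $q_x$ is large).

Over 40 years at the population level (200 patients starting at 87),
cumulative incremental cost deepens to about −300k EUR in the first decade
and then drifts back toward −278k: once the control cohort is nearly
extinct, the intervention's longer-lived survivors keep incurring (lower)
drug and review costs, so the cumulative curve is *not* globally monotone —
a structural consequence of deprescribing extending life, familiar in
health economics as survival-driven cost accrual. Cumulative QALY gains are
non-negative and non-decreasing throughout.

## Verification strategy and problem sizes

The engine is checked against an independent exhaustive path-enumeration
oracle (all $3^{h+1}$ state paths, scalar products of transition
probabilities) on 100 random parameter draws at horizons up to 3, at
tolerance $10^{-12}$; probability conservation and dead-state monotonicity
are asserted on every draw. The boxes algorithm is checked against
brute-force day-by-day unit accumulation on 1,000 random prescriptions
including the 365-day cap. ICER classification is checked against a sign
table on random $(\Delta C, \Delta E)$ pairs, and NMB-sign/acceptance
coherence on QALY-gaining ratio cases. These sizes keep the full suite
under half a minute while exercising every code path; they are choices of
this package, not of the underlying analysis.

## Limitations

The synthetic life table and prescription plans emulate the *shape* of
real inputs, not their values: passing tests demonstrate the model logic
and the robustness of the dominance classification, not the euro-accurate
size of savings for any real population. Effectiveness inputs (survival,
incidence, utilities) are taken as given parameters — the model does not
estimate them from patient-level data, and carries no uncertainty
(no probabilistic sensitivity analysis). Costs are healthcare-system
drug-related costs only; societal costs are excluded. The model has no
tunnel states or time-in-state dependence, and cycles are fixed at one
year.
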