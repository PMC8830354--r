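---
title: "A Markov decision model for two small unruptured intracranial aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov decision model for two small unruptured intracranial aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miamarkov)
```

## The decision problem

Small (<7 mm) unruptured intracranial aneurysms rupture rarely, so elective
coiling of a single small aneurysm is usually hard to justify. A patient who
carries *two* small aneurysms (a multiple-intracranial-aneurysm, MIA,
carrier) is different in two ways: the per-patient risks of aneurysm growth
and rupture are substantially higher than for single-aneurysm carriers, and
a clinician can respond with a wider menu of strategies. `miamarkov`
implements a decision-analytic comparison of six of them for a 57-year-old
carrier of two small unruptured aneurysms:

* `natural_history` — no treatment, no imaging;
* `treat_one` / `treat_two` — elective endovascular coiling of one or both
  aneurysms at the decision point;
* `follow_up_1y` / `follow_up_2y` / `follow_up_5y` — MRA surveillance at the
  given interval, coiling an aneurysm once growth is seen.

Effectiveness is measured in discounted quality-adjusted life-years (QALYs);
no costs are modelled, so the comparison is effectiveness-only.

## Model structure

The model is a nine-state Markov cohort with 1-year cycles, run from age 57
until age 99 (43 cycles). The states are the five "well" states (intact
carrier; carrier with a growing aneurysm; treated patient with a growing
remaining aneurysm; fully recovered with one treated; fully recovered with
both treated), SAH (subarachnoid haemorrhage), permanent mild disability
(mRS 2), permanent moderate-to-severe disability (mRS 3–5) and death.

Conventions that matter and are not uniquely dictated by the problem:

* **Competing events within a cycle** are composed sequentially in the fixed
  order *background death → rupture → growth/detection → de novo formation*,
  as conditional probabilities. Any fixed order is auditable; this one puts
  the largest hazards first.
* **SAH is a one-cycle tunnel state.** The cycle of the bleed is lived at
  utility 0.64; at its end the patient is coiled (both aneurysms) and moves
  to death (0.35), mild (0.15) or moderate-to-severe disability (0.09), or
  full recovery (0.41). Ruptures in every arm use this branch.
* **Screening happens at the end of a cycle.** A cohort member who occupies a
  growing state during cycle *t* is detected and coiled in the transition
  into cycle *t + 1* when a visit is due then; no screening occurs at cycle
  0 (the decision point). A patient who grows under annual surveillance
  therefore spends exactly one cycle exposed to the growing-aneurysm rupture
  rate before treatment.
* **Post-treatment surveillance is asymmetric across arms.** Treated, fully
  recovered patients are followed annually everywhere, but what the visit
  can trigger differs by strategy definition: in `treat_one` it detects
  growth of the remaining untreated aneurysm *and* de novo aneurysms, while
  in the follow-up arms the post-treatment visits detect de novo aneurysms
  only, so a remaining aneurysm that starts growing there stays exposed to
  the growing rupture rate. This reading of the strategy definitions is what
  places `treat_one` above `follow_up_1y` in the base case; under a fully
  symmetric reading annual follow-up would edge ahead of electively treating
  one aneurysm (16.54 vs 16.49 QALYs with the bundled life table).
* **Disability states are terminal apart from death**: no further aneurysm
  events and no re-screening, with background mortality multiplied by 2.02
  (mild) or 4.46 (moderate-to-severe), capped at 1.
* **Risk ratios multiply annual probabilities** (`min(1, RR * p)`) rather
  than acting on hazards; `default_settings(hazard_transform = TRUE)`
  switches to `1 - (1 - p)^RR`. At these magnitudes the difference is in the
  third decimal of an EV. The growing-aneurysm rupture rate (0.063/year) is
  treated as already describing a growing aneurysm and is *not* additionally
  scaled by the MIA rupture risk ratio; `rr_on_growing = TRUE` flips that.
* **De novo aneurysms** (rate 0.003/year, risk ratio 3.92 for MIA carriers)
  are detected at the annual post-treatment visit and treated immediately
  with the one-aneurysm outcome branch, returning the patient to the prior
  treated state on full recovery.
* **Discounting** is `(1.03)^-t` with `t = 0` at entry and no half-cycle
  correction, so a 43-year annuity at utility 1 is worth
  `sum(1.03^-(0:42)) = 24.698` QALYs — the engine reproduces this closed
  form to 1e-10 in the no-event, no-mortality limit.
* **Procedure disutility**: every coiling (entry, detection-triggered, de
  novo, post-SAH) removes 5% of the utility earned in the arrival cycle by
  the mass that flowed through the procedure.

## Parameters and their uncertainty

`default_parameter_table()` encodes the published point estimates, ranges
and distribution families for the 18 clinical parameters and 3 non-trivial
utilities. Beta rows are sampled by matching moments
(`beta_from_moments()`), lognormal rows by ratio-scale moment matching
(`lognormal_from_moments()`; the source table gives the SD on the ratio
scale, and we match it there rather than on the log scale). Utilities are
triangular with mode at the point estimate and the published range as
support — so a sampled utility's mean (e.g. 0.437 for moderate-to-severe)
deliberately differs from its mode (0.41). Draws are not truncated to the
published ranges; the ranges drive only the one- and two-way sweeps.

Two special cases:

* *Mortality after treating one aneurysm* has mean 0 (no deaths among 129
  treated patients) with SD 0.001. A zero-mean beta is undefined, so PSA
  draws use an epsilon mean of 0.0005; the base case keeps the exact 0.
* Joint draws whose branch probabilities (death + mild + moderate-severe)
  exceed 1 are renormalised and counted (`n_renormalised`); at the default
  SDs this essentially never happens.

## The life table

The background mortality source used by the original analysis (a national
census life table, cause-adjusted) is not published, so the package bundles
a Gompertz fixture `q(age) = a e^{b age}` anchored at q(57) = 0.005 and
q(85) = 0.08 and cause-deletes a configurable SAH fraction (default 0.003)
to avoid double-counting rupture deaths. Any CSV life table can be
substituted via `read_life_table()`.

This anchoring is deliberately on the light side: its discounted utility-1
annuity at age 57 is 18.03 QALYs, whereas published base-case values around
15.4 QALYs for the best strategy imply a heavier schedule (annuity near
16.6). Consequently the model reproduces the published *structure* — the
full strategy ranking, the 0.25-QALY gain of treating both over treating
one, all four decision thresholds, the PSA frequencies — while its absolute
QALY levels sit about 1.2–1.4 QALYs above the published ones. Users who
care about absolute levels should supply their target population's life
table; every relative result in this vignette is insensitive to that choice
within plausible bounds.

## Sensitivity analyses

* `run_psa()` draws all distributed parameters jointly (independently across
  parameters) and evaluates all six strategies per draw; 10,000 iterations
  take well under a minute. `optimal_frequencies()` reports how often each
  strategy attains the maximum EV (ties broken by the fixed order
  treat_two, treat_one, annual, biennial, five-yearly, natural history);
  `pairwise_preference()` reports the head-to-head rate between the two
  leading arms — these are different estimands and both are reported.
  `psa_stability()` repeats the PSA over seeds and compares the spread of
  the leading frequency with its binomial standard error.
* `one_way_sweep()` and `tornado_analysis()` sweep each parameter over its
  published range with everything else at the point estimates, recording
  the decision-model EV and whether the optimal strategy switches.
* `threshold_search()` brackets a switch point by coarse scan plus
  bisection (default bracket 1e-4); a dense-grid scan is used as an
  independent oracle in the test suite. With the defaults the four switch
  parameters and their thresholds are: moderate-to-severe disability after
  treating two aneurysms 0.072 (treat_two → treat_one), mortality after
  treating two 0.025, moderate-to-severe after treating one 0.030
  (treat_one → treat_two), and growing-aneurysm rupture rate 0.018 (below
  which natural history overtakes).
* `two_way_grid()` maps the optimal strategy over the Cartesian product of
  two ranges; on the default grids the two elective-treatment arms occupy
  most of the (disability-after-one × disability-after-two) plane.

## The synthetic cohort generator

`generate_treatment_cohort()` emulates the patient-level registry behind
the treatment-outcome rows: outcomes drawn independently from the branch
distributions at the configured sizes (defaults 129 one-treated, 95
two-treated), ages normal around 55.98 (SD 9.99). It reproduces the
*sampling* structure of such a registry — independent categorical outcomes,
binomial uncertainty whose SDs at the real sizes match the published SD
column — but none of its confounding: no case mix, no operator effects, no
correlation between age and outcome. Passing the recovery tests (estimates
within 3 binomial SEs of the generating proportions at n = 1e5) therefore
validates the estimation arithmetic, not the realism of any particular
registry.

## Problem sizes and numerical choices

The analysis scripts and tests use: 43-cycle deterministic runs
(milliseconds), PSA at 10,000 iterations with a 10-seed stability check,
41-point tornado sweeps, 1e-5 threshold brackets against 1e4-point grid
oracles, and 41×41 two-way grids. Transition rows are validated to sum to
1 within 1e-12; cohort rows within 1e-9. The vectorised engine and the
state-by-state audited path (`run_cohort()` + `discounted_qalys()`) are
held equal to 1e-12 on fuzzed parameters by the test suite.

The command-line surface of the package is the set of numbered scripts
under `analysis/`, thin drivers over the exported functions; they are the
intended way to rerun the full analysis sequence.

## Known limitations

* Cohort-level only: no individual-level heterogeneity or microsimulation.
* No costs, so no cost-effectiveness ratios or acceptability curves.
* Perfect MRA detection of growth; no false positives, no loss to
  follow-up, no retreatment after coil compaction.
* Parameter draws are independent; any real-world correlation between, say,
  the two elective outcome branches is ignored.
* Absolute QALY levels inherit the bundled life-table fixture, as discussed
  above.
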