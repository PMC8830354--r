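# miamarkov

A decision-analytic Markov cohort model for the management of **two small
(<7 mm) unruptured intracranial aneurysms** in one patient. Small aneurysms
rupture rarely, but carriers of multiple aneurysms grow and rupture them at
several times the single-aneurysm rates, and clinicians can respond with
anything from watchful waiting to coiling both lesions electively. The
package compares six strategies — natural history, elective coiling of one
or of both aneurysms, and MRA follow-up at 1-, 2- or 5-year intervals — for
a 57-year-old carrier, in discounted quality-adjusted life-years (QALYs).

## The model

A nine-state annual-cycle cohort model run from age 57 to 99:

```
well (2 intact MIAs) ──grow──► well, growing MIA ──(screen)──► coil one
        │                           │
     rupture                     rupture (0.063/y)
        ▼                           ▼
       SAH (tunnel, u = 0.64) ──► coil both: full recovery / mRS 2 / mRS 3-5 / death
```

plus the post-treatment states (one / both treated, remaining aneurysm
growing) and the two permanent disability states. Per cycle, competing
events compose in the order *background death → rupture → growth/detection
→ de novo formation*. Annual rates for the intact carrier are the
single-aneurysm rates scaled by the MIA risk ratios (growth 0.026 × 3.47,
rupture 0.005 × 2.08); a growing aneurysm ruptures at 0.063/year. Elective
coiling outcomes come from a 224-patient registry (e.g. death 0.011 and
moderate-to-severe disability 0.053 after coiling both); SAH coiling uses
death 0.35 / mild 0.15 / moderate-severe 0.09. Utilities: well 1, SAH 0.64,
mild disability 0.72, moderate-to-severe 0.41, with a temporary 5%
disutility in any cycle entered through a coiling procedure. QALYs are
discounted 3%/year. Background mortality is a bundled Gompertz life-table
fixture (q(57) = 0.005, q(85) = 0.08), cause-deleted for SAH deaths; any
`age,q` CSV can be substituted.

Parameter uncertainty follows the published table: beta distributions by
moment matching (`beta_from_moments`), lognormal risk ratios matched on the
ratio scale, triangular utilities, with the published ranges driving the
one- and two-way sweeps. See `vignettes/decision-model.Rmd` for every
modelling convention and its rationale.

## Worked example

```r
library(miamarkov)

params <- load_base_parameters()     # built-in parameter table
life   <- build_fixture_table()      # Gompertz life-table fixture

evaluate_strategies(params, life)
#>          strategy    qalys
#> 1       treat_two 16.74665
#> 2       treat_one 16.49373
#> 3    follow_up_1y 16.38316
#> 4    follow_up_2y 16.32929
#> 5    follow_up_5y 16.17076
#> 6 natural_history 15.56061
```

Coiling both aneurysms is the most effective strategy and natural history
the least; every active strategy beats watchful waiting, and shorter
follow-up intervals do better. The treat-both advantage over treating one
is 0.253 QALYs. (Absolute levels depend on the life table: with the light
bundled fixture they sit ~1.3 QALYs above analyses that used a heavier
census table; the ranking, gaps and thresholds do not.)

```r
psa <- run_psa(params, life, n_iterations = 10000, seed = 1)
optimal_frequencies(psa)
#>       treat_two       treat_one    follow_up_1y    follow_up_2y
#>           65.37           21.11            9.26            0.00
#>    follow_up_5y natural_history
#>            0.00            4.26
pairwise_preference(psa, "treat_two", "treat_one")
#> [1] 71.62
```

So treating both is optimal in about two-thirds of parameter draws and
beats treating one head-to-head in ~72% — the decision is close between
the two elective arms. Where exactly it flips:

```r
threshold_search("modsev_after_treat_two", params, life)$threshold
#> [1] 0.07229407
```

If more than ~7.2% of two-aneurysm coilings end in moderate-to-severe
disability (base estimate 5.3%), treating one aneurysm becomes the better
choice. The other switch parameters are mortality after treating two
(threshold 0.025), moderate-to-severe disability after treating one
(0.030) and the growing-aneurysm rupture rate (0.018).

The full analysis sequence lives in `analysis/01_base_case.R` …
`analysis/05_synthetic_cohort.R`; each script prints what it finds and
writes its tables under `results/`.

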