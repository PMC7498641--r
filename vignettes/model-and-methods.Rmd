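---
title: "Model and methods: vitamin D supplementation to prevent rickets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: vitamin D supplementation to prevent rickets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdcea)
```

## The decision problem

The package evaluates a public-health programme that offers Healthy Start
vitamin D supplements free of charge to pregnant women and children under
4 years of age, with an accompanying promotion/administration budget, to
prevent nutritional rickets. Because skin pigmentation strongly modifies
vitamin D synthesis and hence rickets risk, the analysis is run separately
for light, medium and dark skin-tone subgroups of one region's under-4
population. The comparator is current practice (supplements exist but
uptake is low); the effectiveness unit is the QALY; the decision rule is
the NICE threshold of £20,000–£30,000 per QALY.

## Model structure and assumptions

The model is a two-arm cohort decision tree evaluated in annual cycles.

**Stage 1 (ages 0–3).** Children free of rickets contract it each year
with the subgroup's annual risk, applied conditionally on no earlier
onset; the intervention arm multiplies the risk on the odds scale by the
programme's odds ratio (0.41), a single effect that covers both prenatal
and postnatal supplementation. Onset charges the subgroup's mean treatment
cost once and replaces the age-adjusted baseline utility with the rickets
utility (0.621) for the rickets duration (2 years, pro-rated in a final
part-year and truncated at the horizon). All-cause mortality applies at
the end of each cycle. The base case stops here (4-year horizon) and, by
assumption, has no lifelong complications.

**Stage 2 (lifetime scenario, to age 100).** Survivors are partitioned by
two independent attributes: lifelong complications (probability 10% among
rickets cases; 5% utility decrement plus an annual management cost for
life) and vitamin D deficiency (population prevalence, identical in both
arms because supplementation and deficiency rates are assumed to return to
baseline after the programme ends; 0.2% utility decrement from age 67.04;
mortality relative risk 1.05 from age 76.92). Because deficiency is
arm-independent it cancels exactly from incremental results; it matters
only for absolute levels.

Path probabilities are conserved at every cycle (alive states plus
cumulative deaths sum to one), and `evaluate_arm()` retains a per-cycle
audit trace so accrual choices can be inspected.

## Parameters

All parameters live in a registry tibble (`default_parameters()`), each
with a deterministic point estimate, the SD reported in its evidence
source, and the sampling distribution used in probabilistic sensitivity
analysis. Key values and conventions:

* utilities and durations: rickets utility 0.621 (beta(30.64, 18.70)),
  duration 2 y (gamma(100, 0.02)), deficiency disutility 0.2%, complication
  disutility 5%, complication frequency 10%;
* intervention: rickets OR 0.41 (lognormal), baseline uptake 41.00%
  (women) and 9.64% (children), uptake increases 17% and 20%;
* subgroup annual risks from case counts over a 6-year observation window
  (2, 29 and 25 cases) divided by census denominators (17,344, 14,117 and
  4,952 children) — the window is an explicit input because the published
  per-year counts are rounded; the sampling distribution is gamma with
  shape equal to the case count, the Poisson-count uncertainty;
* subgroup treatment costs £1,750 / £2,385 / £7,305 (2016–17 prices) with
  the 10%-of-mean assumed-SD rule (`assumed_sd()`) and gamma sampling (the
  observed SDs, up to £16,208, are reported but not sampled);
* supplement prices £0.74 and £1.52 per 56-day pack; administration budget
  £10,000/year spread over 36,413 children.

Two published conventions required a decision. First, lognormal parameters
are printed as natural-scale mean and SD (e.g. 0.41; 0.34), so the package
moment-matches them to the log scale by default; a `lognormal_scale =
"log"` switch reads them as meanlog/sdlog instead. Second, several printed
beta parameter pairs are inconsistent with the printed SDs (beta(30.64,
18.70) has analytic SD 0.068, not 0.18) and one is inconsistent with its
printed mean (beta(4104, 42656) has mean 8.78%, not 9.64%). The registry
reproduces the printed values on both surfaces — points deterministically,
printed distributions probabilistically — and
`registry_consistency_report()` flags every mismatch rather than silently
"fixing" either.

## Numerical choices

* **Discounting**: 3.5%/year for costs and QALYs (NICE reference case; the
  source analysis states no rate), configurable including 0%.
* **Cycle accrual**: cycle-start by default; half-cycle correction via
  `timing = "mid"`. The choice is inspectable through the audit trace.
* **Gender mix**: QALYs are a 50/50 male/female mixture by default.
* **Baseline utility**: the published EQ-5D-3L algorithm
  `0.950857 − 0.000259·age² + 0.021213·gender` is implemented exactly as
  printed, clipped to [0, 1] (the quadratic reaches zero near age 62); a
  `utility_form = "population_norm"` switch substitutes the conventional UK
  norm regression with linear and quadratic age terms for plausible
  old-age utilities. Both forms are exercised by the qualitative
  acceptance checks.
* **Payer coverage**: whose supplements the NHS pays for is not stated;
  the default `"incremental"` policy costs only the programme-induced
  uptake increase, with `"all-supplemented"` and `"universal"` options.
* **Pregnancy supplementation**: 270 days, which reproduces the published
  £3.57 per pregnancy from £0.74/56-day packs. The children's £9.90/year
  computes to £9.907; rounding happens only at the report layer.
* **Threshold analysis** bisects the sign of net monetary benefit rather
  than the raw ICER (stable near ΔQ = 0), to relative tolerance 1e-6,
  after validating monotonicity on a coarse grid; out-of-bracket crossings
  return `below_range`/`above_range` sentinels.
* **PSA**: parameters sampled independently (no correlation structure is
  published); each parameter draws from a sub-stream seeded by
  (master seed, parameter name), so adding a parameter never perturbs the
  others' draws. Summaries report mean increments, the ICER of means and
  the CEAC; per-sample ICER means and their implausibly tight published
  confidence intervals are not reproduced — NMB quantile intervals are
  reported instead.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces observational datasets with the statistical
structure the estimators assume: Poisson case counts per subgroup
(mean = rate × population × window), right-skewed gamma onset ages
calibrated so 95% of onsets fall before 48 months at mean 21.16 months,
63.16% male cases, gamma treatment costs matching each subgroup's
mean/SD, and tariff line items that sum exactly to each case total. It
does **not** simulate case-confirmation biochemistry (25OHD, ALP, PTH),
seasonal or spatial structure, or the real per-case cost distribution
shape (only "skewed" is known; gamma is a modelling choice). The onset-age
SD is reported in summaries but not jointly enforced — a two-parameter
gamma cannot match mean, SD and a quantile simultaneously, and the
analysis uses only the mean and the under-48-month share. A green
round-trip test therefore establishes that the estimator/generator pair is
consistent, not that the generator reproduces every feature of real data.

The bundled life table (`synthetic_life_table()`) and the tariff price
list (`tariff_fixture()`) are likewise stylised synthetic stand-ins,
flagged as such in their documentation: no life table or tariff database
is named or redistributable. The stage-2 complication management cost
(£500/year) and deficiency prevalence (0.23, the background figure for
England and Wales) are configurable defaults chosen once; deficiency
parameters cancel from all incremental results.

## Known limitations

* Published absolute cost and QALY levels per arm are not reproducible
  from the printed inputs under any standard discounting/accrual/mixture
  combination (e.g. ≈3.334 QALYs over a 4-year horizon is below any
  discounted baseline-utility annuity). The package therefore treats
  absolute levels as calibration-dependent and validates the printed
  *incremental* ICERs, the distribution/costing/epidemiology anchors, and
  the qualitative decision pattern — dark dominant, medium near £20,000,
  light far above — which all hold across the calibration knobs.
* Threshold-table and PSA-table entries inherit that calibration
  dependence; they are checked against internal brute-force oracles (grid
  scans, per-sample loops), not against the published absolute entries.
* No value-of-information analysis, no multi-comparator frontier, no
  age/sex standardisation of incidence, and no parameter correlation in
  the PSA (a rank-correlation hook is left for future use).

## A complete run

```{r, eval = FALSE}
library(vitdcea)
cea_basecase()                    # deterministic base case, three subgroups
cea_scenario()                    # lifetime scenario vs base case
psa <- run_psa(subgroup = "medium", n_samples = 10000, master_seed = 1)
glance(psa); autoplot(psa); plot_ceac(psa)
tornado(subgroup = "medium")      # univariate sweeps, ordered
threshold_search(default_parameters(), "or_rickets", "medium",
                 lambda = 20000, bracket = c(0.05, 0.99))
cea_run("outputs", what = "all", seed = 1)   # CSV tables + manifest
```
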