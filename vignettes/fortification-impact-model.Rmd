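---
title: "Modelling cancer-mortality impact and economics of vitamin D food fortification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cancer-mortality impact and economics of vitamin D food fortification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdfort)
```

`vdfort` chains four small models — evidence pooling, dose response, burden,
economics — into a scenario grid that answers one question: *if a country
fortified foods with vitamin D so that average daily intake rose by
400–1000 IU, how many cancer deaths and how much money would that plausibly
save per year?* The packaged defaults calibrate the worked example to
Germany in 2016. This vignette records the modelling assumptions, the
parameters that matter, what the synthetic data do and do not emulate, and
the numerical conventions — so that a green test suite can be read for what
it actually establishes.

## 1. Evidence pooling

The effect of vitamin D on cancer mortality comes from five randomized
trials of *supplementation* (the fortification effect is assumed
transferable via the serum pathway, an assumption discussed in §6). Each
trial contributes a relative risk with a 95% CI; nothing else about the
trials enters the math.

```{r}
keum2019_studies()[, 1:4]
pool_random_effects(keum2019_studies())
```

Choices, and why:

* **DerSimonian–Laird, truncated at zero.** The source meta-analyses state
  only "random-effects"; DL with CI-derived standard errors reproduces
  their printed 0.87 (0.79–0.96) from the printed per-study CIs, which is
  the only per-study data available (event counts are not printed).
* **z = 1.96 throughout**, both for CI→SE inversion and the pooled CI. No
  Knapp–Hartung adjustment, no Student-t quantile: with k = 5 a t-based CI
  would be wider than the published one.
* **Zero-width CIs are rejected**, not given infinite weight: a study
  claiming no sampling error is a data error, not a certainty.
* **Leave-one-out** (`leave_one_out()`) exists because one of the five
  trials used bolus + monthly dosing in a vitamin-D-replete population;
  dropping it leaves the point estimate at 0.87, which is the relevant
  robustness check before building a national program on the estimate.

The observed heterogeneity is Q ≈ 0.59 on 4 degrees of freedom, so
τ̂² = 0 and the random-effects fit coincides with the fixed-effect fit —
the tests assert this equality exactly, because it is an algebraic
consequence, not a coincidence.

## 2. Dose response

Two separate mappings, deliberately kept apart:

* **Serum:** Δ25(OH)D = (dose/40) × slope nmol/L. The slope is the one
  genuinely contested parameter; three literature values are packaged
  (`serum_model("table5" | "supplementation" | "fortification")` = 2.0,
  1.95, 1.2 nmol/L per µg/day). The default is 2.0: the published scenario
  table's serum column (+20/+30/+40/+50 nmol/L for 400–1000 IU) is only
  consistent with the rounded slope, so that is what the reproduction uses.
  Whether fortified-food intake really delivers the supplementation slope
  (2.0) or the lower fortification estimate (1.2) is the main scientific
  uncertainty of the whole exercise; the serum column is descriptive and
  does not feed the mortality arithmetic, which runs on dose directly.
* **Mortality:** RRR(d) interpolates linearly between the three per-dose
  trial anchors (400, 0.11), (800, 0.15), (2000, 0.17) — one trial each,
  not a fitted curve, so a spline or Emax model would pretend to knowledge
  that does not exist. Outside 400–2000 IU the function *refuses* rather
  than clamps: below the smallest and above the largest trial dose there is
  no evidence about shape, and silent clamping would manufacture a
  plateau. The pooled flat 13% (`rrr_from_pooled()`) is exposed for
  cross-checks but not used in the grid.

The interpolated RRR is rounded half-up to 0.1 percentage point *before*
any downstream use. This is not cosmetic: the published 1000 IU scenario
figures chain from exactly 15.3%, not 15.333…%, and reproducing them
requires rounding at this point in the pipeline and nowhere else.

## 3. Burden

`total_yll()` multiplies deaths in each (sex, 5-year age group) cell by
remaining life expectancy at the group midpoint and sums. Conventions the
data source leaves open, fixed here once:

* **Midpoint** of a closed group [lo, hi] is (lo + hi + 1)/2 — the group
  spans hi − lo + 1 years of age (70–74 covers ages 70.0–75.0). The
  open-ended top group uses lo + 2.5 by default (`open_offset`),
  reflecting the short residual expectancy at 85+.
* **Life-table lookup** interpolates linearly between tabulated ages;
  midpoints outside the table raise a coverage error naming the missing
  strata rather than extrapolating survival.
* **Total deaths** default to T = 229,827. This is a *back-solved*
  calibration — the anchor scenario's 25,281 prevented deaths divided by
  its 11% reduction (`calibrate_total_deaths(25281, 0.11)`) — not a
  registry-printed number, and it is labelled as derived everywhere it
  appears.

Display counts are rounded half-up; every chained computation uses the
unrounded value. One published cell (the 13% scenario's 29,877 prevented
deaths) is off by one against *any* single consistent rounding rule
(229,827 × 0.13 = 29,877.51); the tests match it to ±1 and everything else
exactly.

## 4. Economics

Savings = unrounded prevented deaths × 40,000 € end-of-life cancer-care
cost per death (configurable), reported in thousand €. Net savings subtract
the rounded cost from the rounded savings so each output row is internally
consistent in printed units.

Program costs are the weak point of the published inputs: the headline
parameters (0.11 € per person-year at 800 IU, 41% processing losses,
ingredient = 80% of total cost) do not by themselves determine the four
published per-dose totals, because the population basis and fixed-cost
treatment live in an unavailable costing appendix. `cost_model()` therefore
carries both:

* **Overrides** {400: 15,166; 600: 17,493; 800: 19,819; 1000: 22,146} k€ —
  fixture values used by the default grid;
* the **parametric formula**
  cost = unit_cost × (dose/800) / (1 − loss) / share_ingredient ×
  population / 1000, available once a `population` is set, for users
  modelling other countries. A least-squares look at the four published
  totals suggests roughly 11.6 k€ per IU of dose plus ≈10.5 M€ of
  dose-independent cost (documented here, asserted nowhere).

"Processing losses of 41%" admits two readings; the default treats delivery
as production × (1 − 0.41), i.e. production = delivered/(0.59), with
`loss_convention = "multiply"` selectable. The ±20% sensitivity variants
scale the base cost before final rounding, which makes the 600 IU high-cost
cell 20,992 k€ where the source prints 20,991 — an off-by-one from the
authors' unrounded internals, matched to ±1 (together with the net cell
that chains from it).

## 5. Synthetic data: what it emulates, what it does not

The registry inputs behind the burden step (age/sex-stratified cancer
deaths; a period life table) are not shipped with any publication, so the
package generates stand-ins with the *structural* properties the pipeline
relies on:

* `gen_mortality_table()` — 18 five-year groups (0–4 … 85+) × 2 sexes;
  age-at-death weights from a discretized Normal(77, 14) over group
  midpoints, mode in the 75–79 group; 54% of deaths male;
  largest-remainder allocation so the table sums to `total_deaths`
  *exactly*. Deterministic.
* `gen_life_table()` — remaining life expectancy e(x) = max(e₀ − 0.95·x,
  1.5) with e₀ = 78.2 (male) / 83.1 (female), tabulated every 5 years to
  age 95.
* `gen_study_set()` — log-RRs from Normal(θ, τ²), SEs uniform, CIs
  exp(θᵢ ± 1.96 seᵢ); a pure function of its seed that restores the
  caller's RNG state.

Calibration: with T = 229,827 the defaults give total YLL ≈ 2.81 M
person-years, close to the ≈2.79–2.8 M implied by back-solving the
published €-per-life-year column, and every cell of that column is
reproduced within ±1 € (four cells differ by exactly 1 €). The decline
rate was *not* tuned further to force exact equality — the defaults are a
stated world, chosen once for demographic plausibility (the e₀ values are
German 2016 period life expectancies at birth; cancer deaths do peak at
ages 75–79 in aged Western populations).

What a green test therefore establishes: the burden/economics arithmetic is
correct and the published column is consistent with *a* plausible YLL total
near 2.8 M. What it does not establish: agreement with the real German age
distribution of cancer deaths (the generator makes no such attempt — no
cancer-site structure, no cohort effects, no sex-specific age shapes), nor
the registry's exact YLL total, which was never published.

## 6. Known limitations

* The causal premise — fortification lowers cancer mortality like
  supplementation because it raises serum 25(OH)D comparably — is a
  modelling assumption; no trial of fortification with mortality endpoints
  exists, and none is likely.
* Three RRR anchors from one trial each; interpolation between them is a
  transparency choice, not an estimated dose–response curve.
* No discounting of life-years or euros, no QALY/DALY weighting, no
  cancer-site stratification, no competing risks, no benefits beyond cancer
  mortality (fractures, cardiovascular or respiratory outcomes are all
  excluded), and no uncertainty propagation beyond the ±20% cost variants —
  the output is an order-of-magnitude policy illustration, not a
  probabilistic cost-effectiveness analysis.
* End-of-life care cost (40,000 €/death) is a single national average;
  the savings column scales linearly in it.

## Reproducing the scenario table

```{r}
run_grid()
```
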