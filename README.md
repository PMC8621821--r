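# vdfort

Health-impact and cost–savings modelling of population-wide **vitamin D food
fortification** with respect to **cancer mortality**, for epidemiologists and
public-health modellers who want the full chain — trial evidence → serum
response → prevented deaths → euros — as tested, reusable code rather than a
spreadsheet.

## The model

1. **Evidence pooling.** Study-level relative risks RRᵢ with 95% CIs are
   pooled on the log scale by inverse-variance DerSimonian–Laird
   random-effects meta-analysis. Standard errors come from CI inversion,
   seᵢ = (ln hiᵢ − ln loᵢ)/(2·1.96); between-study variance is the moment
   estimator τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)) with fixed-effect
   weights wᵢ = 1/seᵢ²; random-effects weights are wᵢ\* = 1/(seᵢ² + τ²).
   Leave-one-out re-pooling probes sensitivity to the single
   bolus/monthly-dosing trial.
2. **Dose response.** A daily fortification dose d (IU) raises serum
   25-hydroxyvitamin D linearly, Δ25(OH)D = (d/40)·slope nmol/L (default
   slope 2.0 per µg/day; 1.95 for supplementation and 1.2 for fortified-food
   intake are selectable). The relative risk reduction RRR(d) is
   piecewise-linearly interpolated between per-dose trial anchors
   (400 IU → 11%, 800 IU → 15%, 2000 IU → 17%); doses outside 400–2000 IU
   are refused, not extrapolated.
3. **Burden.** Total years of life lost
   YLL = Σ_sex Σ_age-group deaths · e(midpoint); prevented deaths =
   T·RRR and preventable YLL = YLL·RRR, where T is the total annual cancer
   death count (Germany-2016 calibration T = 229,827, back-solved from the
   published anchor scenario).
4. **Economics.** Program cost per dose scenario (±20% sensitivity),
   savings = prevented deaths × 40,000 € end-of-life care cost, net savings,
   savings/cost ratio, and € per life-year saved disregarding savings.
5. **Synthetic data.** Deterministic generators for age/sex-stratified
   mortality tables (largest-remainder allocation, exact totals), declining
   life tables, and simulated study sets with known truth — so every stage
   is testable without registry microdata.

## Worked example

```r
library(vdfort)

pool_random_effects(keum2019_studies())
#> Random-effects pooled RR: 0.87 (0.79-0.96)
#> k = 5 studies, Q = 0.587, tau^2 = 0.0000

leave_one_out(keum2019_studies(), "Scragg 2018")
#> Random-effects pooled RR: 0.87 (0.78-0.96)
#> k = 4 studies, Q = 0.321, tau^2 = 0.0000

run_scenario(400, "base")
#>   dose_iu cost_variant serum_increase_nmol_l  rrr deaths_prevented
#> 1     400         base                    20 0.11            25281
#>   savings_keur cost_keur net_savings_keur eur_per_life_year
#> 1      1011239     15166           996073                49
```

A 13% pooled mortality reduction (RR 0.87) across five trials; a 400 IU/day
fortification program would prevent ~25,281 of 229,827 annual cancer deaths,
saving ~1.011 billion € in end-of-life care against ~15.2 million € program
cost — net savings ~996 million €/year, or 49 € per life-year saved if
savings are disregarded. `run_grid()` produces all 12 (dose × cost-variant)
scenarios; `write_grid()` exports them as CSV.

A small CLI wraps the same operations:

```sh
Rscript -e 'vdfort::vdfort_main()' pool --studies studies.csv
Rscript -e 'vdfort::vdfort_main()' grid --out grid.csv
Rscript -e 'vdfort::vdfort_main()' synth deaths --total 229827 --seed 1 --out deaths.csv
```

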