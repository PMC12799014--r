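# lambdafish

Life-table demography and recovery potential of exploited, age-structured
fish stocks.

Age-structured stock assessments estimate numbers-at-age, catch-at-age,
weight, maturity and natural mortality for each year of a managed stock.
`lambdafish` turns those panels into the standard quantities of
conservation demography, for fisheries scientists and quantitative
ecologists who want to compare stocks on a common demographic footing:

* **Annual life tables** — recruitment rate (recruits per kg of spawning
  biomass, offset by the recruit age), biomass-proportional
  fecundity-at-age, fishing/total mortality as annual proportions
  (F = C/N, Z = F + M, l = 1 − Z), and cumulative survivorship-to-age
  both with and without fishing.
* **Annual population growth rates** from the discrete Euler–Lotka
  (renewal) equation

  1 = Σ<sub>a=ν..ω</sub> λ<sup>−a</sup> s<sub>a</sub> f<sub>a</sub> Δx,

  solved for λ each year; λ_real includes fishing mortality, λ_dem
  excludes it. An iterative calibration adjusts each year's natural
  mortality and fecundity (multiplicative 0.5% steps, M first, then
  fecundity) until λ·N_y reproduces the assessed N_y+1 within tolerance
  (default 5%), so the reconstruction and the assessment tell one story.
* **Cohort metrics** for complete cohorts read along diagonals of the
  calibrated schedules: lifetime reproductive success R0 = Σ s_x f_x
  (1 = replacement, 50:50 sex ratio, no plus group) and generation length
  L_G = Σ x s_x f_x / Σ s_x f_x, each with and without fishing.
* **Density dependence** of λ against relative abundance (proportion of
  maximum observed), via a hierarchical penalized-spline model
  (`log λ ~ s(prop) + s(prop, stock, bs = "fs")` in mgcv), with per-stock
  λ anchors at the minimum, 40% and maximum abundance.
* **Recovery potential** from Monte Carlo doubling-time projections: the
  calibrated annual fecundity and natural-mortality schedules are
  resampled (independently, uniformly with replacement), the F = 0 life
  table solved for λ each projection year, and the proportion of 1000
  trajectories that have doubled recorded over 100 years; stocks classify
  as high (≥75% doubled by year 10), moderate (≥50% by year 20) or low.

A seeded simulator (`generateStock()`) produces assessment-like panels —
cohort survival, spawning-biomass-proportional recruitment with lognormal
variability and infrequent large events, age-selective fishing — plus two
exact fixtures (stationary and geometric growth), so the whole pipeline is
testable without any assessment repository.

## Worked example

```r
library(lambdafish)

st <- generateStock(SimConfig(nYears = 30, seed = 42), stockId = "demo")
series <- lambdaSeries(st)
series
#> LambdaSeries 'demo': 29 years (1981-2009), 29 converged
#>   median lambda_real 1.025, median lambda_dem 1.134

head(as.data.frame(series)[, c("year", "lambda_real", "lambda_dem",
                               "converged", "pred_error")], 4)
#>   year lambda_real lambda_dem converged pred_error
#> 1 1981      0.9482      1.076      TRUE    0.04978
#> 2 1982      1.0934      1.211      TRUE    0.03520
#> 3 1983      1.1340      1.248      TRUE    0.03578
#> 4 1984      1.0681      1.186      TRUE    0.04897
```

Every year converged: λ·N_y matches the assessed next-year total within
the 5% tolerance (`pred_error`). Fishing removes the gap between
λ_dem (median 1.134, the growth the stock could have achieved without
harvest) and λ_real (median 1.025).

```r
coh <- cohortSummary(extractCompleteCohorts(st, series))
head(coh[coh$full_schedules, c("cohort_year", "r0_f", "r0_nof",
                               "lg_f", "lg_nof")], 3)
#>   cohort_year  r0_f r0_nof  lg_f lg_nof
#> 1        1981 1.828  10.49 5.482  8.819
#> 2        1982 2.315  12.18 5.864  8.206
#> 3        1983 3.130  13.41 6.065  7.472

projectDoubling(series, RecoveryConfig(nSims = 1000, seed = 1))
#> RecoveryResult 'demo': high recovery potential
#>   doubled by year 10: 99.3%, by year 20: 100.0%
```

Each 1981 spawner replaced itself 1.8 times over its lifetime under
fishing and would have produced 10.5 spawners without it; fishing also
shortens the mean age of reproduction by about three years. Without
fishing, 99% of resampled trajectories double within 10 years: high
recovery potential.

`runPipeline()` orchestrates all stages over many stocks and writes CSV
tables (per-stock λ series, cohort metrics, density-dependence anchors,
doubling curves, decade and group summaries) plus a JSON run manifest.
A thin CLI over the same functions ships in
`inst/scripts/lambdafish.R` (subcommands `simulate`, `lambdas`,
`cohorts`, `density`, `recovery`, `report`).

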