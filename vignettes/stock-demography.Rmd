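---
title: "Life-table demography of exploited fish stocks with lambdafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-table demography of exploited fish stocks with lambdafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdafish)
```

## The problem

Age-structured stock assessments report, for each year and age class,
estimated numbers, fishery removals, mean weight, maturity, and natural
mortality. These panels contain enough information to reconstruct the
classical objects of population demography — survivorship-to-age and
fecundity-at-age schedules — and hence to ask conservation-biology
questions about harvested marine fishes: how fast could a stock grow each
year, how much of that growth does fishing remove, does growth accelerate
as abundance declines (compensation), and how quickly could a depleted
stock double if fishing stopped?

`lambdafish` implements that pipeline end to end. The central data object
is the `StockTable`, a validated year-by-age panel; every downstream stage
consumes it or objects derived from it.

## Annual life tables

For a stock whose youngest assessed age is $b$ and terminal age is
$\omega$ (treated as true longevity; no plus group), each year $y$ gets a
period life table:

* **Recruitment rate.** $RPS_y = R_y / SSB_{y-b}$, the number of recruits
  (fish entering age $b$ in year $y$) per kilogram of spawning stock
  biomass in the parental year. $SSB = \sum_a W\,Mat\,N$.
* **Fecundity-at-age.** Recruits are attributed to age classes in
  proportion to their spawning biomass (each kilogram of spawning biomass
  is assumed to contribute equally), then divided by spawner numbers
  $NS = Mat \times N$. Algebraically this makes per-spawner fecundity
  $f_{y,a} = W_a \times RPS$ at every age with spawners, and 0 elsewhere.
  Fecundity is offset by one year: recruits observed in year $y+1$ enter
  the renewal equation of year $y$. The attribution conserves recruits:
  $\sum_a f_{y,a} NS_a$ equals the attributed recruit count exactly.
* **Mortality.** Fishing mortality is the annual harvest proportion
  $F = C/N$; total mortality $Z = F + M$; survival $l = 1 - Z$. All rates
  are annual proportions, not instantaneous rates.
* **Survivorship.** $s_b = 1$ and $s_a = s_{a-1} l_{a-1}$. Fixing
  first-age survivorship at 1 can slightly overstate productivity;
  `backfillYoungAges()` provides the sensitivity alternative of
  back-calculating abundance down to age 1 through the natural-mortality
  schedule.

Two survivorship schedules are kept side by side: `sReal` under $Z$
(fishing included) and `sDem` under $M$ only. Both use the same fecundity,
so the two growth rates below differ only through fishing deaths.

## The Euler-Lotka equation and calibration

The annual growth rate solves the discrete renewal equation

$$1 = \sum_{a=\nu}^{\omega} \lambda^{-a}\, s_a\, f_a \,\Delta x,
\qquad \Delta x = 1,$$

whose left side is strictly decreasing in $\lambda$, so the positive root
is unique; it equals the dominant eigenvalue of the corresponding Leslie
matrix (this equivalence is a standing test, checked to $10^{-8}$ relative
on a thousand random schedules). The root is bracketed in
$[10^{-6}, 10^{3}]$ and refined by Brent's method to an absolute tolerance
of $10^{-12}$.

Observation error in the assessment series propagates into the
reconstructed schedules in ways that are hard to quantify. The package
therefore anchors each year's $\lambda$ to the assessed series itself:
predicted abundance $\lambda_y N_y$ is compared with the assessed
$N_{y+1}$ (totals over ages), and while the relative discrepancy exceeds
the tolerance (default 5%), the year's schedules are nudged — one
multiplicative step (default 0.5%) on natural mortality at all ages, a
re-check, then one step on fecundity, alternating. Over-prediction raises
$M$ and lowers fecundity; under-prediction does the opposite. Fishing
mortality is never adjusted. Multiplicative steps preserve positivity; if
an $M$ step pushes $Z \ge 1$, survival clamps at a configurable floor
($10^{-6}$) and the fecundity steps carry the remaining adjustment. A year
that exhausts `maxIterations` is flagged non-converged, never an error.
The finer 0.05% step is available (`CalibrationConfig(step = 0.0005)`)
and is required when the tolerance is tightened below the per-step effect
on $\lambda$, otherwise the loop can straddle the acceptance band.

The realized rate $\lambda_{real}$ uses `sReal`; the fishing-excluded
$\lambda_{dem}$ is then solved from the *adjusted* $M$ and fecundity, so
both rates reflect one reconstruction. $\lambda_{dem} \ge \lambda_{real}$
always, with equality exactly when $F \equiv 0$. Because the calibration
reproduces abundance ratios, analytic bounds follow: a stock at half its
maximum whose next year is the maximum must calibrate to $\lambda = 2$, at
a quarter to $4$, and $\lambda \le 1$ in an interior maximum-abundance
year. These bounds are the backbone of the acceptance tests. The terminal
year has no successor and gets no $\lambda$.

```{r fixture}
st <- makeStationaryFixture()
series <- lambdaSeries(st)
round(range(series@lambdaReal), 6)   # exactly replacement
round(series@lambdaDem[1], 6)        # about 1.106 without fishing
```

## Cohort metrics

Complete cohorts — birth-year classes observed at every age $b..\omega$
within the span — are read along the diagonals of the calibrated per-year
tables. Lifetime reproductive success $R_0 = \sum_x s_x f_x$ and
generation length $L_G = \sum_x x\,s_x f_x / \sum_x s_x f_x$ are computed
both under $Z$ and under $M$ only. Setting $F = 0$ removes direct fishing
deaths but not fishing's imprint on the observed age structure, so the
no-fishing variant is a partial counterfactual by construction. Under the
assumed 50:50 sex ratio the per-spawner units cancel (one recruit per
spawner is one female recruit per female spawner), so no factor of one
half is applied; $R_0 = 1$ is replacement on either reading.

Completeness is judged on the data span. The youngest complete cohort
reaches its last age in the terminal data year, whose fecundity is
unknowable (it would need the following year's recruits); that cohort is
kept, flagged `fullSchedules = FALSE`, with NA metrics rather than being
silently dropped.

## Density dependence

Each converged stock-year contributes an observation (proportion of
maximum observed total abundance, $\lambda$). The package fits

`log(lambda) ~ s(prop) + s(prop, stock, bs = "fs")`

with `mgcv::gam` under REML: a global penalized cubic spline (10 basis
functions) plus per-stock factor-smooth deviations (5 basis functions)
sharing one smoothing penalty, i.e. smooth curves treated as random
effects. Modelling $\log\lambda$ with Gaussian errors is operationally a
lognormal response model and numerically stabler. The known
heteroskedasticity and non-normality of such data defeat more elaborate
error models, so the fit is used descriptively — global curve, per-stock
curves, and per-stock anchors at the minimum observed proportion, at 40%
of maximum, and at the maximum — with no significance testing of the
smooths. The 40% anchor is reported NA for stocks that never fell to 40%
of their maximum. mgcv flags the global-plus-deviation structure as
"repeated 1-d smooths"; the warning is muffled deliberately since the
shared-penalty construction is the point. If smoothing-parameter
estimation fails on degenerate data (a constant response, for instance),
the model refits with heavy fixed penalties, shrinking every smooth
towards the parametric fit.

## Recovery potential

`projectDoubling()` resamples the calibrated annual schedules: for each
trajectory and projection year it draws one observed year's fecundity
vector and, independently, one observed year's natural-mortality vector
(uniform with replacement; no fecundity-mortality correlation is
imposed, and the draw is refreshed every projection year), builds the
$F = 0$ life table, solves for $\lambda$, and multiplies relative
abundance (initialized at 1 — only ratios matter). Doubling is absorbing,
so the proportion-doubled curve is nondecreasing and measures the earliest
possible doubling time. No density dependence is applied. Since $\lambda$
depends only on the (mortality-year, fecundity-year) pair, it is
precomputed for all pairs and trajectories reduce to cumulative sums of
sampled $\log\lambda$, which keeps 1000 trajectories over 100 years
essentially instant.

Classification: **high** if at least 75% of trajectories doubled by year
10; else **moderate** if at least 50% doubled by year 20; else **low**. A
stock reaching 75% only by year 20 is moderate — the high class is defined
strictly at year 10.

```{r recovery}
res <- projectDoubling(series, RecoveryConfig(nSims = 500, seed = 1))
res@propDoubled[6:8]   # constant lambda 1.106 doubles exactly in year 7
res@classification
```

## The synthetic-stock generator

Real assessment repositories cannot ship with a package, so the generator
produces panels with the statistical structure the analysis assumes:
cohort survival with proportional rates ($M + F < 1$ enforced), catch
$F \times N$ with no mid-year timing adjustment, recruitment proportional
to lagged spawning biomass with mean-corrected lognormal noise, and an
independent Bernoulli large-event multiplier standing in for the
infrequent strong year classes that sustain many harvested stocks (the
phenomenon is well documented; the lognormal-times-Bernoulli form is this
package's choice of stand-in). Defaults — ages 1-10, $M = 0.2$, logistic
maturity at age 3, logistic selectivity to 0.35, recruitment CV 0.6,
8-fold events at probability 0.1, 40-year series, mean recruitment rate
0.4 recruits/kg chosen just above replacement under fishing — describe a
moderately long-lived demersal stock with series lengths typical of
well-assessed stocks. Two exact fixtures, a stationary stock and a
geometric-growth stock (knife-edge maturity makes both exactly
self-consistent), pin the hand-checkable identities.

What the generator does **not** emulate: assessment observation error and
retrospective revisions, time-varying weight/maturity/selectivity,
environmental covariates, spatial or multispecies structure, and
stock-recruit depensation. Passing tests therefore demonstrate that the
method recovers the demography of data whose generating process matches
its assumptions — not that assessment output for any particular real stock
is error-free.

## Numerical and design choices

* Proportional (annual) mortality throughout; survival floor $10^{-6}$
  when $Z \ge 1$, always flagged.
* Fecundity basis: per-spawner (recruits per mature spawner), as the
  attribution construction defines it. With partial maturity a per-capita
  reading (multiplying by maturity) is also defensible; both are
  implemented (`basis = "perCapita"`), per-spawner is the default, and the
  two coincide under knife-edge maturity. For stocks with $b > 1$ the
  recruit-offset indexing is applied as "recruits observed in year $y+1$
  enter the renewal equation of year $y$".
* Ages with no spawners get fecundity 0 (not NaN); zero-abundance ages get
  $F = 0$ with a flag.
* Calibration alternates single steps, M first; adjustments are recorded
  as net multipliers per year.
* Decade summaries bin by calendar decade labelled by start year, use
  sample SD, and summarize $r$ as medians of $\log\lambda$ (not logs of
  median $\lambda$); medians interpolate at even counts.
* Monte Carlo projections derive per-stock seeds from the master seed, so
  any stock's result is reproducible in isolation.

## Problem sizes

The test suite runs the fixtures plus property sweeps sized to stay quick
while exercising every invariant: 200-1000 random schedules for the
Leslie-eigenvalue equivalence, 20 generated stocks of 40 years for the
calibration contract, 1000 trajectories for the recovery fixture, and 100
replicate fits of 12 stocks by 20 years for interval coverage of the
density-dependence smooth. The full suite completes in well under a
minute on a single core.

## Limitations

The reconstruction treats assessment output as observations; model-based
abundance estimates carry their own assumptions and the calibration
inherits them. $\lambda_{dem}$ is not a maximum intrinsic growth rate:
the age structure it acts on is still shaped by fishing. Unreported
removals would surface here as lowered fecundity or raised natural
mortality during calibration. The density-dependence fit is descriptive,
and the doubling-time projection ignores density dependence, which is
conservative at low abundance if compensation is real.
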