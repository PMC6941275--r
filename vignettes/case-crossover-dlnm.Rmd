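---
title: "Case-crossover DLNM: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-crossover DLNM: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagrisk)
```

## The scientific problem

Acute events such as ischemic stroke may be triggered by short-term exposure
to air pollution, with two complications that defeat a plain regression of
daily counts on same-day concentrations. First, the exposure-response
relationship is often non-linear — threshold ("J"-shaped) patterns for
primary pollutants, and sometimes "V"-shaped patterns where both low and
high concentrations carry risk. Second, the effect is *distributed over
lags*: today's risk reflects the past two weeks of exposure, not one day.
At the same time, both the event rate and the exposures are strongly
seasonal, so any naive comparison is confounded by time.

`lagrisk` combines the two standard answers. The **time-stratified
case-crossover design** compares each day only with other days in the same
calendar month of the same year, so slowly varying confounders (season,
trend, and population-level characteristics) cancel by design; estimated as
a Poisson regression with stratum fixed effects, it is exactly the
conditional-likelihood case-crossover. The **distributed lag non-linear
model (DLNM)** represents the exposure effect as a smooth surface
`s(x, l)` over exposure value and lag, parameterised by the tensor product
of two spline bases — the *cross-basis*.

## Model and estimation

For day $t$, event count $Y_t$ and year-end population $\mathrm{Pop}_{ye}$:

$$
\log\!\big(\mu_t / \mathrm{Pop}_{ye}\big)
 = \alpha + \sum_i cb\big(x_{i,t}\big)
 + cb(\mathrm{Temp}_t) + cb(\mathrm{RH}_t)
 + \gamma\,\mathrm{Holiday}_t + \lambda_{\mathrm{stratum}(t)},
\qquad \mathrm{Var}(Y_t) = \phi\,\mu_t .
$$

The cross-basis of an exposure series $x$ with maximum lag $L$ has entries
$W_{t,(j,k)} = \sum_{l=0}^{L} R_j(x_{t-l})\,C_k(l)$, with $R$ a natural
cubic spline basis over the exposure range and $C$ one over the integer
lags. Columns are ordered exposure-index-outer, lag-index-inner, and the
knots are stored with the object so any contrast can be reproduced exactly.
The first $L$ rows have incomplete lag history; they are flagged and
excluded from the fit rather than imputed, the standard DLNM practice.

Estimation is Poisson IRLS with the log-population offset. The dispersion
$\hat\phi$ is the Pearson statistic over residual degrees of freedom (the
standard quasi-Poisson estimator, rather than the deviance-based one), and
scales the inverse Fisher information to give the coefficient covariance.
Aliased columns are dropped deterministically in first-kept order and
reported. Model comparison uses
$\mathrm{QAIC} = -2\,\ell/\hat\phi + 2p$; when candidates are compared, the
dispersion of the most complex candidate can be supplied to `qaic()` so all
models are penalised on a common scale — a convention, since quasi-likelihood
theory does not fix the choice.

Two routes to the stratum effects are provided and tested for equivalence:
explicit indicator columns (mirroring the written model equation, the
default), and a conditional route that profiles the stratum effects out in
closed form each Newton step — given the other coefficients, the stratum
effect that matches observed to expected stratum totals is
$\hat\lambda_s = \log(\sum_{t \in s} y_t / \sum_{t \in s} e^{\eta_{0t}})$ —
and solves the step on within-stratum weighted-centred columns. The two give
identical non-stratum estimates up to numerical precision; the conditional
route is faster when the stratum count is large.

## Effects

All reported quantities are linear contrasts of the cross-basis
coefficients. For a contrast of exposure `at` against reference `ref`
accumulated over lags $l_0..l_1$, the contrast vector is
$c_{(j,k)} = [R_j(at) - R_j(ref)] \sum_{l=l_0}^{l_1} C_k(l)$, the log-RR is
$c^\top\hat\beta$, and the delta-method SE is
$\sqrt{c^\top \hat V c}$ with the dispersion-scaled covariance block. CIs
use the exact normal multiplier 1.959964. The reference is the median of
the *analysed* (post-mask) series, and the extreme contrasts use its 1st
and 99th percentiles; percentiles are computed by linear interpolation
between order statistics (R's default type 7). At a sample size of ~2,500
days the pre- vs post-mask distinction is negligible, but using the
analysed rows keeps every reported number a function of the data actually
fitted. Exposures outside the observed range are rejected rather than
extrapolated.

## Design choices

Where the design was genuinely open, the package resolves it as follows.

* **Knot placement.** Exposure knots at equally spaced quantiles of the
  observed series (df 3 puts them at the 33.3rd/66.7th percentiles); lag
  knots equally spaced on the log-lag scale between lag 1 and $L$, with
  boundary knots at 0 and $L$. Both follow the de-facto DLNM convention and
  are recorded on the `cross_basis` object.
* **Lag-basis intercept.** The exposure basis carries no intercept (the
  model intercept and strata absorb level, and contrasts set the reference),
  but the lag basis *does* include a constant column. An effect spread
  uniformly over lags is a lag-constant surface; it multiplies the exposure
  basis, so no global intercept can absorb it, and an intercept-free lag
  basis would exclude exactly the surfaces of greatest scientific interest.
  `df_lag` counts the intercept, so a 3x3 cross-basis still has 9 columns.
* **Stratum definition.** Year x calendar month (84 strata over seven
  years). A `stratum_by = "year_month_dow"` switch additionally stratifies
  on day of week, off by default to mirror the plain month-stratum model.
* **Offset.** The log year-end population is retained even though the
  year-month strata nearly absorb it — fidelity to the written equation; a
  constant offset shift moves only the intercept (tested).
* **Significance screen.** A pollutant enters multi-pollutant candidates
  only if some extreme-contrast cell of its single-pollutant model has a
  95% CI excluding 1 — the operational version of "no significant
  single-pollutant association" used to drop a pollutant.
* **Sensitivity scan.** One dimension at a time (exposure df 2–6, lag df
  2–6, maxlag 12–21) around the base model, matching how such analyses are
  reported; the full factorial grid adds little and multiplies cost.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
exact ground truth for validation.

* **Exposures** are lognormal: `median * exp(seasonal cosine + loading *
  shared factor + AR(1) noise)`, truncated below at 0.1 ug/m3. The log
  scale yields the right-skewed marginals of real monitoring series; the
  shared standard-normal daily factor induces the strong positive
  correlation among primary pollutants; seasonal phase (winter peaks for
  pollutants, summer peaks for temperature and humidity, autumn for ozone)
  produces the observed negative pollutant-meteorology correlations.
* **Counts** are negative binomial with mean
  $\mu_t = \mathrm{Pop}_{ye}\, e^{\eta_t}$ and variance $\phi\,\mu_t$
  (Poisson when $\phi = 1$): quasi-Poisson has no generative form and NB
  with this parameterisation is the standard stand-in. The linear predictor
  adds a seasonal baseline cosine (amplitude 0.15, winter peak) so the
  stratum terms have genuine confounding to remove, a holiday shift of
  −0.05 on fixed days-of-year, and the lagged effect surfaces.
* **Effect surfaces** are piecewise-linear hinges — "J" (zero below a
  threshold, linear above) or "V" (additionally rising below a low
  threshold) — with nonnegative lag weights summing to 1, so every
  cumulative log-RR has a closed-form truth
  (`true_cumulative_log_rr()`). Exposures are simulated for a burn-in
  period before the first retained day so all lags are defined from row 1.
* **Subgroups** are independent binomial splits of the total (male 0.595,
  elderly 0.484, echoing typical cohort proportions), adequate because the
  subgroup machinery is exercised for mechanics, not effect-heterogeneity
  recovery.
* **Defaults.** The default study is seven years (2,557 days) of five
  pollutants averaging ~25 events/day with dispersion 3 and a constant
  population of 10 million per year (real year-end denominators are rarely
  published with such analyses; any constant works because the offset is
  absorbed up to the intercept).

What the generator does **not** emulate: spatial (station-level) structure
and exposure measurement error, reporting-delay misalignment between onset
and diagnosis, day-of-week patterns in counts, and effect heterogeneity
across subgroups. Passing validation here therefore shows the estimator is
correct and calibrated for data with this generative structure, not that
any given real dataset satisfies it.

## Validation studies and problem sizes

Three preset configurations drive the validation suite, sized to run in a
few minutes on one core:

* `null_sim_config()` — one null pollutant, dispersion 1, six years.
  Across 200 simulations the Pearson dispersion stays within [0.9, 1.1] and
  the 95% CI for the 99th-vs-median cumulative RR excludes 1 at close to the
  nominal 5% rate.
* `recovery_sim_config()` — one pollutant with a J surface (hinge 16,
  slope 0.026, uniform lags 0–14; true cumulative log-RR ~0.4 at the
  99th-vs-median contrast over lag 0–12, i.e. RR ~1.5, the magnitude of
  headline effects in this literature), dispersion 2, seven years. Across
  200 simulations the mean estimation error stays within 0.05 and CI
  coverage within 95% +/- 3%.
* Shape recovery — averaged fitted exposure-response curves over 50
  simulations reproduce the J and V shapes of the planted truths.

Numerical tolerances used by the unit oracles: cross-basis vs triple-loop
brute force 1e-10; IRLS vs direct likelihood maximisation 1e-6;
indicator-vs-conditional stratum equivalence 1e-6; delta-method SE vs
10,000 multivariate-normal coefficient draws within 2%.

## Known limitations

Robust/sandwich variances, autocorrelation corrections, penalised splines,
attributable-fraction computations and selection-adjusted inference for
"maximum RR across windows" reporting are out of scope. The extreme table
reports every window; picking the largest cell afterwards inherits the
usual selection optimism, which the CIs do not adjust for.
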