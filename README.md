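# lagrisk

Distributed lag non-linear case-crossover analysis of daily event counts.

`lagrisk` is for environmental-epidemiology analyses that ask how a
short-term exposure (air pollutants, temperature) relates to the daily count
of an acute health event (e.g. ischemic stroke onset) when the effect may be
**non-linear in exposure** and **delayed and spread over days**. It
implements the time-stratified case-crossover design estimated as a
quasi-Poisson regression with calendar-month stratum fixed effects, combined
with a distributed lag non-linear model (DLNM), and ships a synthetic
daily-series generator with known ground truth so that the whole pipeline
can be calibrated and validated.

## The model

For day *t* with event count *Y<sub>t</sub>* and year-end population
*Pop<sub>ye</sub>*:

```
Y_t ~ quasi-Poisson(mu_t)
log(mu_t / Pop_ye) = alpha + sum_i cb(x_{i,t}; df_var, maxlag, df_lag)
                   + cb(Temp_t; 3, 3, 3) + cb(RH_t; 3, 3, 3)
                   + gamma * Holiday_t + lambda_stratum(t)
```

`cb()` is the DLNM **cross-basis**: with `R` a natural cubic spline basis
over the exposure range and `C` a natural cubic spline basis over integer
lags `0..L`, row *t*, column *(j,k)* of the cross-basis is
`sum_l R_j(x_{t-l}) C_k(l)`. Its fitted coefficients parameterise a smooth
log-RR surface over (exposure, lag). Defaults follow common practice for
this design: `df_var = df_lag = 3`, `maxlag = 14` days for pollutants and 3
days for meteorology, exposure knots at equally spaced quantiles, lag knots
equally spaced on the log-lag scale. The stratum is the calendar month
within year, so each day is compared only with nearby days, absorbing
seasonality and long-term trend.

Estimation is Poisson IRLS (explicit stratum indicators, or an exactly
equivalent conditional route that profiles the stratum effects out
analytically); the dispersion is estimated from the Pearson statistic and
scales the coefficient covariance; models are compared by Q-AIC. Effects
are reported as relative risks of an exposure contrast (typically the 99th
or 1st percentile vs the median) cumulated over a lag window, with
delta-method 95% CIs. Multi-pollutant models exclude pairs with Spearman
|r| > 0.60.

## Worked example

Simulate seven years of daily data in which an SO2-like pollutant has a
known J-shaped effect (hinge at 16 ug/m3, slope 0.026 per ug/m3 on the
log-RR scale, spread uniformly over lags 0–14), then fit and estimate the
cumulative RR of the 99th-percentile-vs-median contrast:

```r
library(lagrisk)
cfg    <- recovery_sim_config(seed = 7)
series <- generate_series(cfg)
m  <- fit_study_model(series, "SO2")   # SO2 + temperature + humidity + holiday + strata
cb <- m$cbs$SO2
q  <- quantile(cb$x[!cb$incomplete], c(0.5, 0.99), type = 7, names = FALSE)
cumulative_rr(m$fit, cb, at = q[2], ref = q[1], window = c(0, 12))
#>   term   at  ref lag_from lag_to log_rr    se   rr   lo   hi
#> 1  SO2 32.7 11.9        0     12  0.388 0.058 1.47 1.32 1.65
true_cumulative_log_rr(cfg, "SO2", at = q[2], ref = q[1], window = c(0, 12))
#> [1] 0.377
```

The fit uses 2,543 days (the first 14 lack complete lag history), 112
parameters including 84 year-month strata, and a Pearson dispersion of 2.09
(the generator's truth is 2). The estimated cumulative log-RR 0.388 (SE
0.058) brackets the exact ground truth 0.377. The extreme-influence table
mirrors the usual reporting layout:

```r
extreme_influence_table(list(total = m$fit), m$cbs,
                        windows = list(c(0, 6), c(0, 12), c(0, 14)))
#>   pollutant        block  window   rr    lo   hi
#> 1       SO2  extreme_low  lag0-6 1.03 0.908 1.16
#> 2       SO2 extreme_high  lag0-6 1.24 1.142 1.36
#> 3       SO2  extreme_low lag0-12 1.04 0.876 1.24
#> 4       SO2 extreme_high lag0-12 1.47 1.316 1.65
#> 5       SO2  extreme_low lag0-14 1.03 0.844 1.26
#> 6       SO2 extreme_high lag0-14 1.60 1.402 1.83
```

The extreme-high RRs grow with the lag window (the truth accumulates
uniformly over lags) while the extreme-low contrasts stay at the null, as
they should for a J-shaped surface. `run_study()` orchestrates the full
pipeline — descriptives, Spearman screening, single-pollutant screen,
Q-AIC/collinearity model selection, subgroup tables and the df/maxlag
sensitivity scan — and writes every table as CSV.

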