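# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with naive loops / closed forms, never by calling the
# implementation they check.

# Triple-loop cross-basis: W[t,(j,k)] = sum_l R[t-l, j] * C[l+1, k],
# exposure index outer, lag index inner. Rows without full lag history NA.
brute_cross_basis <- function(R, C, maxlag) {
  n <- nrow(R); dv <- ncol(R); dl <- ncol(C)
  W <- matrix(NA_real_, n, dv * dl)
  for (t in (maxlag + 1):n)
    for (j in 1:dv)
      for (k in 1:dl) {
        acc <- 0
        for (l in 0:maxlag) acc <- acc + R[t - l, j] * C[l + 1, k]
        W[t, (j - 1) * dl + k] <- acc
      }
  W
}

# Double-loop lagged-exposure matrix.
brute_lag_matrix <- function(x, maxlag) {
  n <- length(x)
  Q <- matrix(NA_real_, n, maxlag + 1)
  for (t in 1:n)
    for (l in 0:maxlag)
      if (t - l >= 1) Q[t, l + 1] <- x[t - l]
  Q
}

# Hand-written Poisson log-likelihood with offset for the tiny fixtures.
brute_poisson_loglik <- function(beta, X, y, offset) {
  mu <- exp(offset + drop(X %*% beta))
  sum(y * log(mu) - mu - lgamma(y + 1))
}

# Six-day two-stratum fixture with one binary exposure column, used by the
# likelihood-oracle and hand-contrast tests.
six_day_fixture <- function() {
  y <- c(3, 7, 4, 9, 2, 6)
  X <- cbind(`(Intercept)` = 1,
             exposure = c(0, 1, 0, 1, 0, 1),
             stratum2 = c(0, 0, 0, 1, 1, 1))
  offset <- log(c(10, 10, 12, 12, 11, 11))
  list(y = y, X = X, offset = offset)
}

# Small one-pollutant simulated series for fitting/effects fixtures.
quick_series <- function(seed = 7, n_days = 500, effect = TRUE,
                         dispersion = 2) {
  eff <- if (effect)
    effect_surface("J", threshold_high = 16, slope_high = 0.02,
                   lag_weights = rep(1 / 15, 15))
  cfg <- sim_config(
    seed = seed, n_days = n_days, dispersion = dispersion,
    pollutants = list(
      pollutant_spec("SO2", 12, 0.35, 0.85, 0.14,
                     shared_factor_loading = 0.28,
                     effect = if (effect) eff)))
  generate_series(cfg)
}
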