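# Generator: determinism, null-effect calibration, ground-truth consistency.

test_that("same config and seed give a byte-identical series", {
  cfg <- default_sim_config(seed = 11, n_days = 400)
  s1 <- generate_series(cfg)
  s2 <- generate_series(cfg)
  expect_identical(s1, s2)
  s3 <- generate_series(default_sim_config(seed = 12, n_days = 400))
  expect_false(identical(s1$total, s3$total))
})

test_that("null effects with dispersion 1 give plain Poisson counts around the analytic mean", {
  cfg <- sim_config(
    seed = 3, n_days = 2192, dispersion = 1,
    baseline_seasonal_amplitude = 0, holiday_effect = 0,
    pollutants = list(pollutant_spec("P", 12, 0.3, 0.8, 0.15)))
  s <- generate_series(cfg)
  mu <- 1e7 * exp(cfg$baseline_log_rate)  # constant analytic mean
  expect_true(abs(mean(s$total) - mu) < 3 * sqrt(mu / nrow(s)))
  # Pearson statistic over df near 1 under Poisson truth
  pearson <- sum((s$total - mu)^2 / mu) / nrow(s)
  expect_gt(pearson, 0.9)
  expect_lt(pearson, 1.1)
})

test_that("stored mu matches an independent row-by-row recomputation", {
  cfg <- recovery_sim_config(seed = 21, n_days = 400)
  s <- generate_series(cfg)
  truth <- attr(s, "truth")
  p <- cfg$pollutants$SO2
  w <- p$effect$lag_weights
  x <- truth$exposures_ext[, "SO2"]
  burn <- truth$burn_in
  f <- function(v) p$effect$slope_high * max(v - p$effect$threshold_high, 0)
  doy <- as.integer(format(s$date, "%j"))
  mu_oracle <- numeric(nrow(s))
  for (t in seq_len(nrow(s))) {
    contrib <- 0
    for (l in seq_along(w) - 1) contrib <- contrib + w[l + 1] * f(x[burn + t - l])
    eta <- cfg$baseline_log_rate +
      cfg$baseline_seasonal_amplitude * cos(2 * pi * (doy[t] - 15) / 365.25) +
      cfg$holiday_effect * s$holiday[t] + contrib
    mu_oracle[t] <- s$population[t] * exp(eta)
  }
  expect_lt(max(abs(mu_oracle - truth$mu) / truth$mu), 1e-10)
})

test_that("high-exposure episodes raise the mean count under a J surface", {
  cfg <- recovery_sim_config(seed = 5, n_days = 1500)
  s <- generate_series(cfg)
  # 15-day trailing mean exposure drives the lagged uniform-weight surface
  ma <- stats::filter(s$SO2, rep(1 / 15, 15), sides = 1)
  ok <- !is.na(ma)
  hi <- ma[ok] > quantile(ma[ok], 0.8)
  lo <- ma[ok] < quantile(ma[ok], 0.2)
  expect_gt(mean(s$total[ok][hi]), mean(s$total[ok][lo]))
})

test_that("subgroup splits reconcile with the total on every row", {
  s <- generate_series(default_sim_config(seed = 8, n_days = 400))
  expect_identical(s$male + s$female, s$total)
  expect_identical(s$elderly + s$adult, s$total)
  expect_true(all(s$total >= 0))
  expect_true(all(vapply(c("SO2", "NO2", "PM10", "CO", "O3"),
                         function(p) all(s[[p]] > 0), TRUE)))
  expect_true(all(s$humidity >= 0 & s$humidity <= 100))
  expect_identical(as.integer(diff(s$date)), rep(1L, nrow(s) - 1L))
})

test_that("true cumulative log-RR follows the surface arithmetic", {
  cfg <- sim_config(
    seed = 1, n_days = 400,
    pollutants = list(
      pollutant_spec("P", 50, 0.3, 0.8, 0.15,
                     effect = effect_surface("J", threshold_high = 50,
                                             slope_high = 0.01,
                                             lag_weights = rep(1 / 15, 15)))))
  # hand sum: 15 terms of 0.01 * (100 - 50) * (1/15) each -> 0.5
  expect_equal(true_cumulative_log_rr(cfg, "P", at = 100, ref = 40,
                                      window = c(0, 14)), 0.5,
               tolerance = 1e-12)
  expect_identical(true_cumulative_log_rr(cfg, "P", at = 80, ref = 80,
                                          window = c(0, 5)), 0)
  expect_identical(true_cumulative_log_rr(cfg, "P", at = 45, ref = 30,
                                          window = c(0, 14)), 0)
  expect_error(true_cumulative_log_rr(cfg, "P", at = 100, ref = 40,
                                      window = c(0, 15)), "window")
  expect_error(true_cumulative_log_rr(cfg, "Q", at = 1, ref = 0), "unknown")
})

test_that("cross-pollutant Spearman correlation increases with the loading product", {
  mean_corr <- function(loading) {
    mean(vapply(1:10, function(seed) {
      cfg <- sim_config(
        seed = seed, n_days = 400,
        pollutants = list(
          pollutant_spec("A", 12, 0.2, 0.8, 0.15,
                         shared_factor_loading = loading),
          pollutant_spec("B", 40, 0.2, 0.8, 0.15,
                         shared_factor_loading = loading)))
      s <- generate_series(cfg)
      spearman_matrix(s, c("A", "B"))["A", "B"]
    }, numeric(1)))
  }
  r <- vapply(c(0.05, 0.15, 0.35), mean_corr, numeric(1))
  expect_true(all(r > 0))
  expect_true(all(diff(r) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_days = 100, pollutants = list(
    pollutant_spec("P", 10, 0.3, 0.8, 0.1))), "366")
  expect_error(pollutant_spec("P", 10, 0.3, 1.0, 0.1), "ar_coefficient")
  expect_error(effect_surface("J", threshold_high = 10, slope_high = 0.1,
                              lag_weights = c(0.5, 0.4)), "sum to 1")
  expect_error(sim_config(n_days = 400, pollutants = list(
    pollutant_spec("P", 10, 0.3, 0.8, 0.1)),
    population_by_year = c("2008" = 1e7)), "population")
})

test_that("series round-trips through CSV and validation catches gaps", {
  s <- generate_series(default_sim_config(seed = 2, n_days = 400))
  path <- tempfile(fileext = ".csv")
  write_daily_series(s, path)
  s2 <- read_daily_series(path, pollutants = c("SO2", "NO2"))
  expect_equal(s2$SO2, s$SO2, tolerance = 1e-12)
  expect_identical(s2$date, s$date)
  bad <- as.data.frame(s)[-5, ]
  expect_error(validate_daily_series(bad), "consecutive")
  expect_error(validate_daily_series(as.data.frame(s)[, -2]),
               "missing column")
})
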