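# Contrast algebra, delta-method intervals and the extreme-influence table.

make_fit <- function(seed = 12) {
  s <- quick_series(seed = seed, n_days = 500)
  m <- fit_study_model(s, "SO2")
  m$series <- s
  m
}

test_that("a null contrast gives RR exactly 1 with a degenerate CI", {
  m <- make_fit()
  est <- cumulative_rr(m$fit, m$cbs$SO2, at = 12, ref = 12, window = c(0, 14))
  expect_identical(est$rr, 1)
  expect_identical(est$se, 0)
  expect_identical(c(est$lo, est$hi), c(1, 1))
})

test_that("cumulative log-RR is the sum of single-lag log-RRs", {
  m <- make_fit()
  cb <- m$cbs$SO2
  cum <- cumulative_rr(m$fit, cb, at = 20, ref = 10, window = c(0, 14))
  singles <- vapply(0:14, function(l)
    lag_specific_rr(m$fit, cb, at = 20, ref = 10, lag = l)$log_rr,
    numeric(1))
  expect_equal(cum$log_rr, sum(singles), tolerance = 1e-12)
  # degenerate window equals the lag-specific estimate
  one <- cumulative_rr(m$fit, cb, at = 20, ref = 10, window = c(5, 5))
  lag5 <- lag_specific_rr(m$fit, cb, at = 20, ref = 10, lag = 5)
  expect_equal(one$log_rr, lag5$log_rr, tolerance = 1e-12)
  expect_equal(one$se, lag5$se, tolerance = 1e-12)
})

test_that("hand contrast arithmetic on a 1x1 basis reproduces exp(beta * delta-basis)", {
  fx <- six_day_fixture()
  # replace the binary exposure by a 1x1 cross-basis of a continuous series
  x <- c(2, 7, 4, 9, 3, 8)
  cb <- build_cross_basis(x, df_var = 1, df_lag = 1, maxlag = 0,
                          series_id = "expo")
  fx$X[, "exposure"] <- cb$matrix[, 1]
  colnames(fx$X)[2] <- "expo.v1.l1"
  fx$term_index <- list(expo = 2L)
  fit <- fit_quasipoisson(fx)
  est <- lag_specific_rr(fit, cb, at = 8, ref = 3, lag = 0, term = "expo")
  dR <- natural_cubic_basis(c(8, 3), knots = numeric(0), boundary = range(x))
  delta <- dR[1, 1] - dR[2, 1]
  expect_equal(est$rr, unname(exp(unname(fit$coefficients[2]) * delta)),
               tolerance = 1e-10)
  expect_error(lag_specific_rr(fit, cb, at = 20, ref = 3, lag = 0,
                               term = "expo"), "boundary")
})

test_that("doubling a linear-basis contrast doubles the log-RR", {
  x <- seq(0, 10, length.out = 40)
  cb <- build_cross_basis(x, df_var = 1, df_lag = 1, maxlag = 0,
                          series_id = "e")
  set.seed(4)
  y <- rpois(40, exp(1 + 0.1 * x))
  fit <- fit_quasipoisson(list(y = y,
                               X = cbind(`(Intercept)` = 1,
                                         e.v1.l1 = cb$matrix[, 1]),
                               offset = rep(0, 40),
                               term_index = list(e = 2L)))
  a <- lag_specific_rr(fit, cb, at = 6, ref = 4, lag = 0, term = "e")
  b <- lag_specific_rr(fit, cb, at = 8, ref = 4, lag = 0, term = "e")
  expect_equal(b$log_rr, 2 * a$log_rr, tolerance = 1e-10)
})

test_that("delta-method SE agrees with multivariate-normal simulation", {
  m <- make_fit(seed = 13)
  cb <- m$cbs$SO2
  est <- cumulative_rr(m$fit, cb, at = 20, ref = 10, window = c(0, 12))
  idx <- m$fit$term_index$SO2
  V <- m$fit$vcov[idx, idx]
  set.seed(99)
  # draw coefficient vectors and recompute the contrast for each draw
  ch <- chol(V + 1e-12 * diag(nrow(V)))
  draws <- matrix(rnorm(10000 * nrow(V)), 10000) %*% ch
  cvec <- lagrisk:::cb_contrast(cb, at = 20, ref = 10, lags = 0:12)
  sim_se <- sd(draws %*% cvec)
  expect_lt(abs(sim_se - est$se) / est$se, 0.02)
})

test_that("the exposure-response curve passes through RR 1 at the reference", {
  m <- make_fit(seed = 14)
  cb <- m$cbs$SO2
  curve <- overall_curve(m$fit, cb, grid = c(8, 10, 12, 16), ref = 12)
  expect_identical(curve$rr[curve$at == 12], 1)
  expect_equal(nrow(curve), 4)
  lrc <- lag_response_curve(m$fit, cb, at = 20, ref = 10)
  expect_equal(nrow(lrc), 15)
})

test_that("extreme-influence table honours its invariants", {
  m <- make_fit(seed = 15)
  tab <- extreme_influence_table(list(total = m$fit), m$cbs)
  expect_s3_class(tab, "extreme_influence_table")
  expect_true(all(tab$lo <= tab$rr & tab$rr <= tab$hi))
  expect_equal(tab$rr, exp(tab$log_rr), tolerance = 1e-12)
  expect_equal(tab$lo, exp(tab$log_rr - 1.959964 * tab$se), tolerance = 1e-12)
  # reference column is the observed post-mask median throughout
  xobs <- m$cbs$SO2$x[!m$cbs$SO2$incomplete]
  expect_equal(unique(tab$ref), quantile(xobs, 0.5, type = 7, names = FALSE))
  # at-exposure = median gives RR exactly 1 in every cell
  tab50 <- extreme_influence_table(list(total = m$fit), m$cbs,
                                   probs = c(0.5, 0.5, 0.5))
  expect_true(all(tab50$rr == 1))
  # degenerate series rejected
  cbc <- build_cross_basis(rep(1, 500) + 1e-12 * 0, df_var = 1, df_lag = 1,
                           maxlag = 0, series_id = "const",
                           var_boundary = c(0, 2))
  expect_error(extreme_influence_table(list(total = m$fit),
                                       list(const = cbc)), "degenerate")
})

test_that("CI width grows with the lag window on nested cumulative contrasts", {
  m <- make_fit(seed = 16)
  cb <- m$cbs$SO2
  widths <- vapply(list(c(0, 6), c(0, 10), c(0, 14)), function(w)
    cumulative_rr(m$fit, cb, at = 20, ref = 10, window = w)$se, numeric(1))
  expect_true(all(diff(widths) > 0))
})
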