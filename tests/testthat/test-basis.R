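# Spline basis, lag matrix and cross-basis construction.

test_that("basis dimensions follow the df bookkeeping", {
  x <- runif(200, 0, 50)
  b <- natural_cubic_basis(x, df = 3)
  expect_equal(dim(b), c(200, 3))
  expect_length(attr(b, "knots"), 2)  # df = interior knots + 1, no intercept
  b4 <- natural_cubic_basis(x, df = 4, intercept = TRUE)
  expect_length(attr(b4, "knots"), 2)  # df = knots + 1 + intercept
  expect_error(natural_cubic_basis(x, knots = c(30, 20), boundary = c(0, 50)),
               "increasing")
  expect_error(natural_cubic_basis(x, knots = c(60), boundary = c(0, 50)),
               "inside")
})

test_that("every basis column is linear beyond the boundary knots", {
  set.seed(1)
  x <- runif(100, 0, 10)
  b <- natural_cubic_basis(x, df = 4, boundary = c(0, 10))
  for (x0 in c(-3, 12.5)) {  # points beyond either boundary
    h <- 1e-3
    pts <- natural_cubic_basis(c(x0 - h, x0, x0 + h),
                               knots = attr(b, "knots"),
                               boundary = c(0, 10))
    d2 <- pts[1, ] - 2 * pts[2, ] + pts[3, ]  # second-order finite difference
    expect_lt(max(abs(d2)), 1e-8)
  }
})

test_that("linear functions lie in the span of the basis plus intercept", {
  set.seed(2)
  x <- sort(runif(300, 0, 100))
  b <- natural_cubic_basis(x, df = 3)
  # least-squares projection oracle: residual of x on [1, basis]
  fitted <- qr.fitted(qr(cbind(1, b)), x)
  expect_lt(max(abs(fitted - x)), 1e-8)
})

test_that("lag matrix matches the hand-readable and brute-force constructions", {
  x <- c(1, 2, 3, 4)
  expect_equal(build_lag_matrix(x, 0)[, 1], x)
  Q <- build_lag_matrix(x, 2)
  expect_equal(unname(Q[4, ]), c(4, 3, 2))
  expect_true(all(is.na(Q[1, 2:3])))
  set.seed(3)
  xr <- rnorm(60)
  expect_equal(unname(build_lag_matrix(xr, 14)), brute_lag_matrix(xr, 14))
  expect_error(build_lag_matrix(xr, 60), "length")
})

test_that("constant exposure makes every complete cross-basis row R(c) x colSums(C)", {
  n <- 40
  cb <- build_cross_basis(rep(5, n), df_var = 3, df_lag = 3, maxlag = 7,
                          var_knots = c(3, 6), var_boundary = c(0, 10))
  W <- cb$matrix[!cb$incomplete, ]
  expect_lt(max(apply(W, 2, function(col) diff(range(col)))), 1e-12)
  R <- natural_cubic_basis(5, knots = c(3, 6), boundary = c(0, 10))
  C <- natural_cubic_basis(0:7, knots = cb$lag_knots, boundary = c(0, 7),
                           intercept = TRUE)
  expected <- as.vector(t(outer(drop(R), colSums(C))))
  expect_equal(unname(W[1, ]), expected, tolerance = 1e-12)
})

test_that("3 x 3 cross-basis has 9 columns and maxlag flagged rows", {
  s <- quick_series(seed = 4, n_days = 500)
  cb <- build_cross_basis(s$SO2, df_var = 3, df_lag = 3, maxlag = 14)
  expect_equal(ncol(cb$matrix), 9)
  expect_equal(sum(cb$incomplete), 14)
  expect_true(all(is.finite(cb$matrix[!cb$incomplete, ])))
})

test_that("cross-basis equals the triple-loop brute force and is bilinear", {
  set.seed(5)
  x <- runif(80, 0, 30)
  cb <- build_cross_basis(x, df_var = 3, df_lag = 3, maxlag = 14)
  R <- natural_cubic_basis(x, knots = cb$var_knots,
                           boundary = cb$var_boundary)
  C <- natural_cubic_basis(0:14, knots = cb$lag_knots,
                           boundary = c(0, 14), intercept = TRUE)
  W <- brute_cross_basis(R, C, 14)
  expect_lt(max(abs(W - unname(cb$matrix)), na.rm = TRUE), 1e-10)
  # linearity in the exposure basis: a * R scales W by a
  expect_equal(brute_cross_basis(2.5 * R, C, 14), 2.5 * W,
               tolerance = 1e-12)
})

test_that("a single constant lag column reduces to the moving-average model", {
  set.seed(6)
  x <- runif(60, 0, 20)
  L <- 5
  cb <- build_cross_basis(x, df_var = 3, df_lag = 1, maxlag = L)
  expect_equal(ncol(cb$matrix), 3)
  # direct construction: moving sum of each exposure-basis column
  R <- natural_cubic_basis(x, knots = cb$var_knots, boundary = cb$var_boundary)
  ms <- apply(R, 2, function(col)
    stats::filter(col, rep(1, L + 1), sides = 1))
  keep <- !cb$incomplete
  expect_equal(unname(cb$matrix[keep, ]), unname(ms[keep, ]),
               tolerance = 1e-10)
})
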