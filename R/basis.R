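# Natural cubic spline bases and the bi-dimensional exposure-lag cross-basis.

#' Natural cubic spline basis
#'
#' Evaluates a natural cubic spline basis (cubic between knots, C2-continuous,
#' linear beyond the boundary knots) at the supplied values. The basis columns
#' span the space of natural cubic splines on the given knots (plus a constant
#' when `intercept = TRUE`); individual column values are an implementation
#' detail of the B-spline-derived parameterisation used for numerical
#' conditioning.
#'
#' With `intercept = FALSE`, `df = length(knots) + 1`; with
#' `intercept = TRUE`, `df = length(knots) + 2`. When `knots` is `NULL` they
#' are placed at `df`-dependent equally spaced quantiles of `x`
#' (probabilities `(1:nk)/(nk + 1)`), and the boundary defaults to
#' `range(x)`.
#'
#' @param x numeric vector of evaluation points (finite).
#' @param df basis dimension (number of columns). Ignored when `knots` is
#'   given.
#' @param knots interior knot locations, strictly increasing and strictly
#'   inside the boundary.
#' @param boundary length-2 numeric, the boundary knots.
#' @param intercept logical; include a constant column in the basis.
#' @return numeric matrix with `length(x)` rows and `df` columns, with
#'   attributes `knots`, `Boundary.knots` and `intercept` recording the basis
#'   so it can be re-evaluated at new points.
#' @export
natural_cubic_basis <- function(x, df = NULL, knots = NULL, boundary = NULL,
                                intercept = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be a finite numeric vector")
  if (is.null(boundary)) boundary <- range(x)
  if (length(boundary) != 2 || boundary[1] >= boundary[2])
    stop("'boundary' must be two increasing values")
  if (is.null(knots)) {
    if (is.null(df)) stop("supply either 'df' or 'knots'")
    nk <- df - 1L - as.integer(intercept)
    if (nk < 0) stop("'df' too small for the requested basis")
    knots <- if (nk > 0)
      unname(stats::quantile(x, probs = seq_len(nk) / (nk + 1), type = 7))
    else numeric(0)
  }
  if (length(knots) > 0) {
    if (any(diff(knots) <= 0)) stop("'knots' must be strictly increasing")
    if (any(knots <= boundary[1]) || any(knots >= boundary[2]))
      stop("'knots' must lie strictly inside the boundary")
  }
  b <- splines::ns(x, knots = knots, Boundary.knots = boundary,
                   intercept = intercept)
  out <- matrix(as.numeric(b), nrow = length(x))
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  attr(out, "knots") <- as.numeric(knots)
  attr(out, "Boundary.knots") <- as.numeric(boundary)
  attr(out, "intercept") <- intercept
  out
}

#' Matrix of lagged exposures
#'
#' Builds the n x (L+1) matrix `Q` with `Q[t, l+1] = x[t - l]` for lags
#' `l = 0..L`. Entries whose lag reaches before the start of the series are
#' `NA` (rows `t <= L` have incomplete lag history).
#'
#' @param x numeric exposure series.
#' @param maxlag maximum lag `L >= 0`.
#' @return numeric matrix with columns named `lag0..lagL`.
#' @export
build_lag_matrix <- function(x, maxlag) {
  n <- length(x)
  maxlag <- as.integer(maxlag)
  if (maxlag < 0) stop("'maxlag' must be >= 0")
  if (maxlag >= n) stop("'maxlag' must be smaller than the series length")
  Q <- matrix(NA_real_, n, maxlag + 1L,
              dimnames = list(NULL, paste0("lag", 0:maxlag)))
  for (l in 0:maxlag)
    Q[(l + 1L):n, l + 1L] <- x[seq_len(n - l)]
  Q
}

# Interior knots equally spaced on the log-lag scale between lag 1 and L,
# the usual DLNM convention for concentrating flexibility at short lags.
log_lag_knots <- function(maxlag, nk) {
  if (nk <= 0) return(numeric(0))
  if (maxlag < 2) stop("log-spaced lag knots need maxlag >= 2")
  exp(seq(log(1), log(maxlag), length.out = nk + 2L))[seq_len(nk) + 1L]
}

#' Build an exposure-lag cross-basis
#'
#' Constructs the bi-dimensional cross-basis of a distributed lag non-linear
#' model: row `t`, column `(j, k)` holds
#' `sum_{l=0}^{L} R_j(x[t - l]) * C_k(l)`, where `R` is a natural cubic
#' spline basis over the exposure range and `C` a natural cubic spline basis
#' over the integer lags `0..L`. Columns are ordered with the exposure index
#' `j` outer and the lag index `k` inner (`v1.l1, v1.l2, ..., v2.l1, ...`).
#'
#' The exposure basis carries no intercept (the reference level is set by the
#' contrast at prediction time); the lag basis includes an intercept column so
#' that effects spread uniformly over lags are inside the model space — the
#' model's global intercept cannot absorb those because they multiply the
#' exposure basis. Exposure knots default to equally spaced quantiles of the
#' series; lag knots to equally spaced values on the log-lag scale with
#' boundary `[0, L]`.
#'
#' The first `maxlag` rows have incomplete lag history: they are `NA` in the
#' matrix and flagged in `$incomplete`, and are excluded from downstream fits.
#'
#' @param x numeric exposure series (one value per consecutive day).
#' @param df_var exposure-dimension basis dimension (default 3).
#' @param df_lag lag-dimension basis dimension, counting the lag intercept
#'   (default 3).
#' @param maxlag maximum lag in days.
#' @param var_knots,var_boundary optional exposure knots / boundary overrides.
#' @param lag_knots optional lag knots override.
#' @param series_id label identifying the exposure (used to name model terms).
#' @return an object of class `cross_basis`: a list with the basis `matrix`
#'   (`df_var * df_lag` columns), the flag vector `incomplete`, the knot
#'   metadata needed to form prediction contrasts, and the exposure series.
#' @export
build_cross_basis <- function(x, df_var = 3, df_lag = 3, maxlag = 14,
                              var_knots = NULL, var_boundary = NULL,
                              lag_knots = NULL, series_id = "exposure") {
  n <- length(x)
  if (maxlag >= n) stop("series length must exceed 'maxlag'")
  if (any(!is.finite(x))) stop("exposure series must be finite")
  if (is.null(var_boundary)) var_boundary <- range(x)
  R <- natural_cubic_basis(x, df = df_var, knots = var_knots,
                           boundary = var_boundary, intercept = FALSE)
  if (df_lag == 1L || maxlag == 0L) {
    # single constant lag column: the moving-average (uniform-lag) model
    C <- matrix(1, maxlag + 1L, 1L)
    attr(C, "knots") <- numeric(0)
    attr(C, "Boundary.knots") <- c(0, maxlag)
    attr(C, "intercept") <- TRUE
  } else {
    if (is.null(lag_knots))
      lag_knots <- log_lag_knots(maxlag, df_lag - 2L)
    C <- natural_cubic_basis(0:maxlag, knots = lag_knots,
                             boundary = c(0, maxlag), intercept = TRUE)
  }
  dv <- ncol(R); dl <- ncol(C)
  W <- matrix(0, n, dv * dl)
  for (l in 0:maxlag) {
    idx <- (l + 1L):n
    Rl <- R[seq_len(n - l), , drop = FALSE]
    for (j in seq_len(dv)) {
      cols <- (j - 1L) * dl + seq_len(dl)
      W[idx, cols] <- W[idx, cols] +
        Rl[, j] %o% C[l + 1L, ]
    }
  }
  incomplete <- seq_len(n) <= maxlag
  if (maxlag > 0) W[incomplete, ] <- NA_real_
  colnames(W) <- paste0("v", rep(seq_len(dv), each = dl),
                        ".l", rep(seq_len(dl), dv))
  structure(
    list(matrix = W,
         incomplete = incomplete,
         df_var = dv, df_lag = dl, maxlag = as.integer(maxlag),
         var_knots = attr(R, "knots"),
         var_boundary = attr(R, "Boundary.knots"),
         lag_knots = attr(C, "knots"),
         lag_boundary = attr(C, "Boundary.knots"),
         lag_const = ncol(C) == 1L,
         series_id = series_id,
         x = x),
    class = "cross_basis")
}

# Re-evaluate the marginal bases of a cross-basis at new points.
cb_var_basis <- function(cb, at) {
  if (any(at < cb$var_boundary[1] - 1e-8) || any(at > cb$var_boundary[2] + 1e-8))
    stop("exposure value outside the basis boundary; no extrapolation")
  natural_cubic_basis(at, knots = cb$var_knots, boundary = cb$var_boundary,
                      intercept = FALSE)
}

cb_lag_basis <- function(cb, lags) {
  if (any(lags < 0) || any(lags > cb$maxlag))
    stop("lag outside 0..maxlag")
  if (isTRUE(cb$lag_const)) return(matrix(1, length(lags), 1L))
  natural_cubic_basis(lags, knots = cb$lag_knots, boundary = cb$lag_boundary,
                      intercept = TRUE)
}

#' @export
print.cross_basis <- function(x, ...) {
  cat("cross_basis for '", x$series_id, "': ", nrow(x$matrix), " days, ",
      x$df_var, " x ", x$df_lag, " = ", x$df_var * x$df_lag,
      " columns, maxlag ", x$maxlag, "\n", sep = "")
  cat("  exposure knots:", format(x$var_knots, digits = 4),
      " boundary:", format(x$var_boundary, digits = 4), "\n")
  cat("  lag knots:", format(x$lag_knots, digits = 4),
      " (log-spaced), incomplete rows:", sum(x$incomplete), "\n")
  invisible(x)
}
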