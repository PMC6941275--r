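# Turning fitted cross-basis coefficients into relative risks:
# lag-specific and cumulative contrasts, exposure-response curves, and the
# extreme-percentile influence tables.

Z95 <- 1.959964  # exact 97.5% normal quantile

# Contrast vector for one (at vs ref) exposure contrast at the given lags,
# in the cross-basis column order (exposure index outer, lag index inner).
cb_contrast <- function(cb, at, ref, lags) {
  dR <- cb_var_basis(cb, at) - cb_var_basis(cb, ref)
  C <- cb_lag_basis(cb, lags)
  Csum <- colSums(C)
  as.vector(t(outer(drop(dR), Csum)))  # j outer, k inner
}

effect_row <- function(fit, cb, term, at, ref, lags) {
  cvec <- cb_contrast(cb, at, ref, lags)
  beta <- term_coef(fit, term)
  V <- term_vcov(fit, term)
  if (length(beta) != length(cvec))
    stop("contrast length does not match the '", term, "' coefficient block")
  log_rr <- sum(cvec * beta)
  se <- sqrt(max(0, drop(cvec %*% V %*% cvec)))
  data.frame(term = term, at = at, ref = ref,
             lag_from = min(lags), lag_to = max(lags),
             log_rr = log_rr, se = se, rr = exp(log_rr),
             lo = exp(log_rr - Z95 * se), hi = exp(log_rr + Z95 * se),
             stringsAsFactors = FALSE)
}

#' Lag-specific relative risk
#'
#' RR of the contrast `at` vs `ref` attributable to a single lag day `lag`:
#' the contrast vector is `(R(at) - R(ref)) (x) C(lag)` applied to the
#' term's coefficient block, with a delta-method standard error from the
#' dispersion-scaled covariance and a 95% CI `exp(log_rr +/- 1.959964 se)`.
#' Exposures outside the basis boundary are rejected (no extrapolation).
#'
#' @param fit a `qp_fit`. @param cb the term's `cross_basis`.
#' @param at,ref exposure values contrasted. @param lag single lag day.
#' @param term coefficient block name (defaults to the basis's series id).
#' @return one-row data frame: `term, at, ref, lag_from, lag_to, log_rr, se,
#'   rr, lo, hi`.
#' @export
lag_specific_rr <- function(fit, cb, at, ref, lag, term = cb$series_id) {
  if (lag < 0 || lag > cb$maxlag) stop("lag outside 0..maxlag")
  effect_row(fit, cb, term, at, ref, lags = lag)
}

#' Cumulative relative risk over a lag window
#'
#' The contrast vector is the sum of the lag-specific contrasts over
#' `window[1]..window[2]`, so the cumulative log-RR is the sum of the
#' single-lag log-RRs and its SE accounts for their covariance.
#'
#' @inheritParams lag_specific_rr
#' @param window integer pair `c(l0, l1)` within `0..maxlag`.
#' @export
cumulative_rr <- function(fit, cb, at, ref, window = c(0, cb$maxlag),
                          term = cb$series_id) {
  if (window[1] < 0 || window[2] > cb$maxlag || window[1] > window[2])
    stop("window outside 0..maxlag")
  effect_row(fit, cb, term, at, ref, lags = window[1]:window[2])
}

#' Cumulative exposure-response curve
#'
#' Cumulative RR over `window` evaluated on a grid of exposure values against
#' a fixed reference; the curve passes through RR = 1 at the reference.
#'
#' @inheritParams cumulative_rr
#' @param grid exposure values (within the basis boundary).
#' @return data frame with one row per grid value.
#' @export
overall_curve <- function(fit, cb, grid, ref, window = c(0, cb$maxlag),
                          term = cb$series_id) {
  out <- do.call(rbind, lapply(grid, function(g)
    cumulative_rr(fit, cb, at = g, ref = ref, window = window, term = term)))
  rownames(out) <- NULL
  out
}

#' Single-day lag-response curve
#'
#' RR of a fixed exposure contrast at each single lag `0..maxlag`.
#'
#' @inheritParams lag_specific_rr
#' @export
lag_response_curve <- function(fit, cb, at, ref, term = cb$series_id) {
  out <- do.call(rbind, lapply(0:cb$maxlag, function(l)
    lag_specific_rr(fit, cb, at = at, ref = ref, lag = l, term = term)))
  rownames(out) <- NULL
  out
}

# Lag windows used for the cumulative-influence tables.
default_windows <- function(maxlag = 14) {
  w <- list(c(0, 1), c(0, 6), c(0, 8), c(0, 10), c(0, 12), c(0, 13), c(0, 14))
  Filter(function(x) x[2] <= maxlag, w)
}

window_label <- function(w) paste0("lag", w[1], "-", w[2])

#' Extreme-influence table
#'
#' For each pollutant and population group, the cumulative RR comparing the
#' pollutant's 1st (extreme-low block) and 99th (extreme-high block)
#' percentiles against its median, over each lag window. Percentiles are
#' computed from the analysed (post-mask) series by linear interpolation of
#' order statistics.
#'
#' @param fits named list of `qp_fit` objects, one per population group
#'   (e.g. `total`, `male`, ...), all sharing the same cross-bases.
#' @param cbs named list of `cross_basis` objects, one per pollutant.
#' @param windows list of lag windows (integer pairs); defaults to
#'   lag0-1 through lag0-14 truncated at each basis's maxlag.
#' @param probs percentile triple `(low, reference, high)`.
#' @return data frame of class `extreme_influence_table`: `pollutant, group,
#'   block, window, at, ref, log_rr, se, rr, lo, hi`.
#' @export
extreme_influence_table <- function(fits, cbs, windows = NULL,
                                    probs = c(0.01, 0.5, 0.99)) {
  if (inherits(fits, "qp_fit")) fits <- list(total = fits)
  if (inherits(cbs, "cross_basis")) cbs <- stats::setNames(list(cbs), cbs$series_id)
  rows <- list()
  for (pn in names(cbs)) {
    cb <- cbs[[pn]]
    xobs <- cb$x[!cb$incomplete]
    if (diff(range(xobs)) < .Machine$double.eps^0.5)
      stop("degenerate (constant) exposure series for ", pn)
    q <- stats::quantile(xobs, probs = probs, type = 7, names = FALSE)
    wins <- if (is.null(windows)) default_windows(cb$maxlag) else
      Filter(function(w) w[2] <= cb$maxlag, windows)
    for (g in names(fits)) {
      if (is.null(fits[[g]]$term_index[[pn]])) next
      for (w in wins) {
        lo_row <- cumulative_rr(fits[[g]], cb, at = q[1], ref = q[2],
                                window = w, term = pn)
        hi_row <- cumulative_rr(fits[[g]], cb, at = q[3], ref = q[2],
                                window = w, term = pn)
        rows[[length(rows) + 1L]] <- data.frame(
          pollutant = pn, group = g,
          block = c("extreme_low", "extreme_high"),
          window = window_label(w),
          rbind(lo_row, hi_row)[, c("at", "ref", "log_rr", "se",
                                    "rr", "lo", "hi")],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("extreme_influence_table", "data.frame")
  out
}

#' Write an effect table or curve as CSV
#'
#' RR and CI bounds are rounded to two decimals in the written report, the
#' conventional table style for this literature; the unrounded values remain
#' in the in-memory object.
#'
#' @param x a data frame of effect estimates. @param path output file.
#' @param digits rounding applied to rr/lo/hi columns (`NULL` for none).
#' @export
write_effect_csv <- function(x, path, digits = 2) {
  out <- as.data.frame(x)
  if (!is.null(digits))
    for (cc in intersect(c("rr", "lo", "hi"), names(out)))
      out[[cc]] <- round(out[[cc]], digits)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
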