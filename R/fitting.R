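# Quasi-Poisson estimation of the case-crossover DLNM:
#   log(mu_t / Population) = alpha + sum_i cb_i + gamma * Holiday + lambda_stratum
# Two numerically equivalent routes are provided: explicit stratum indicator
# columns, and a conditional formulation that profiles the stratum effects
# out analytically and solves the Newton step on within-stratum weighted
# centred columns (the time-stratified case-crossover / Poisson equivalence).

#' Assemble the model design from a daily series and cross-bases
#'
#' The time stratum is the calendar month within year of each date (84 strata
#' over 7 years), encoded as fixed-effect indicators with the first stratum as
#' reference; the offset is the log year-end population of the row's year; the
#' response is the chosen subgroup's count column. Rows whose cross-basis lag
#' history is incomplete (the first `max(maxlag)` rows) are masked out of the
#' fit.
#'
#' @param series a `daily_series` (or equivalent data frame).
#' @param crossbases list of [build_cross_basis()] objects aligned row-for-row
#'   with `series`; names default to each basis's `series_id`.
#' @param subgroup count column to use as response (`"total"`, `"male"`, ...).
#' @param stratum_by `"year_month"` (default, mirroring calendar-month
#'   strata), `"year_month_dow"` to additionally stratify on day of week, or
#'   `"none"`.
#' @return an object of class `design_matrix`: response `y`, full indicator
#'   design `X` (intercept, cross-basis blocks, holiday, stratum dummies),
#'   non-stratum block `Z`, `offset`, `stratum` factor, row `mask`, and
#'   `term_index` mapping each model term to its columns.
#' @export
build_design <- function(series, crossbases, subgroup = "total",
                         stratum_by = c("year_month", "year_month_dow", "none")) {
  stratum_by <- match.arg(stratum_by)
  if (!subgroup %in% names(series))
    stop("no count column '", subgroup, "' in the series")
  if (inherits(crossbases, "cross_basis")) crossbases <- list(crossbases)
  if (is.null(names(crossbases)) || any(!nzchar(names(crossbases))))
    names(crossbases) <- vapply(crossbases, `[[`, "", "series_id")
  n <- nrow(series)
  for (cb in crossbases)
    if (nrow(cb$matrix) != n) stop("cross-basis not aligned to series rows")

  y <- series[[subgroup]]
  offset <- log(series$population)
  mask <- rep(TRUE, n)
  for (cb in crossbases) mask <- mask & !cb$incomplete

  stratum <- switch(stratum_by,
    year_month = factor(format(series$date, "%Y-%m")),
    year_month_dow = factor(paste(format(series$date, "%Y-%m"),
                                  format(series$date, "%u"), sep = "-")),
    none = factor(rep("all", n)))

  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  term_index <- list()
  for (nm in names(crossbases)) {
    B <- crossbases[[nm]]$matrix
    colnames(B) <- paste(nm, colnames(B), sep = ".")
    blocks[[nm]] <- B
  }
  blocks$holiday <- matrix(series$holiday, n, 1,
                           dimnames = list(NULL, "holiday"))
  if (nlevels(stratum) > 1) {
    S <- stats::model.matrix(~ s - 1, data.frame(s = stratum))
    colnames(S) <- paste0("stratum", levels(stratum))
    blocks$stratum <- S[, -1, drop = FALSE]  # first stratum is the reference
  }
  X <- do.call(cbind, blocks)
  pos <- 0L
  for (nm in names(blocks)) {
    term_index[[nm]] <- pos + seq_len(ncol(blocks[[nm]]))
    pos <- pos + ncol(blocks[[nm]])
  }
  nonstratum <- setdiff(names(blocks), c("(Intercept)", "stratum"))
  Z <- X[, unlist(term_index[nonstratum]), drop = FALSE]

  if (!any(mask)) stop("empty design: every row is masked")
  structure(list(y = y, X = X, Z = Z, offset = offset, mask = mask,
                 stratum = stratum, term_index = term_index,
                 crossbases = crossbases, subgroup = subgroup,
                 stratum_by = stratum_by, date = series$date),
            class = "design_matrix")
}

# Drop aliased columns deterministically (first-kept order) via pivoted QR.
drop_aliased <- function(X, tol = 1e-9) {
  qrX <- qr(X, tol = tol)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  list(keep = keep, dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

# Core Poisson IRLS on an explicit design matrix. Returns MLE pieces; the
# quasi-Poisson layer adds Pearson dispersion scaling on top.
qp_irls <- function(X, y, offset, maxit = 100, tol = 1e-10) {
  fit <- stats::glm.fit(X, y, offset = offset, family = stats::poisson(),
                        control = stats::glm.control(epsilon = tol,
                                                     maxit = maxit))
  if (!fit$converged)
    stop("IRLS did not converge in ", maxit,
         " iterations (last deviance ", format(fit$deviance), ")")
  mu <- fit$fitted.values
  grad <- drop(crossprod(X, y - mu))
  if (max(abs(grad)) > 1e-6 * max(1, max(abs(crossprod(X, y)))))
    warning("score not fully converged; max |gradient| = ",
            format(max(abs(grad))))
  list(coefficients = fit$coefficients, mu = mu,
       info = crossprod(X * sqrt(mu)), deviance = fit$deviance,
       iter = fit$iter)
}

#' Fit the quasi-Poisson case-crossover model
#'
#' Maximises the Poisson log-likelihood with offset (IRLS), then estimates
#' the dispersion phi by the Pearson statistic over residual degrees of
#' freedom and scales the coefficient covariance by it. Aliased columns are
#' dropped deterministically (first-kept order) and reported.
#'
#' `method = "indicator"` estimates the stratum effects as explicit columns.
#' `method = "conditional"` profiles them out analytically each Newton step
#' (given the other coefficients, the stratum effect equalising observed and
#' expected stratum totals is available in closed form) and solves the step
#' on within-stratum weighted-centred columns; the two routes agree on the
#' non-stratum coefficients to numerical precision.
#'
#' @param design a [build_design()] object, or a bare list with elements
#'   `y`, `X`, `offset` (and optionally `mask`) for direct low-level fits.
#' @param method `"indicator"` or `"conditional"`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return an object of class `qp_fit`: `coefficients`, dispersion-scaled
#'   `vcov`, `dispersion`, Poisson `loglik`, `n_used`, `p` (number of
#'   estimated parameters including stratum effects), `qaic`, `term_index`
#'   into the coefficient vector, and `dropped` aliased columns.
#' @export
fit_quasipoisson <- function(design, method = c("indicator", "conditional"),
                             maxit = 100, tol = 1e-10) {
  method <- match.arg(method)
  mask <- if (is.null(design$mask)) rep(TRUE, length(design$y)) else design$mask
  y <- design$y[mask]
  offset <- design$offset[mask]
  n_used <- length(y)

  if (method == "indicator" || is.null(design$stratum)) {
    X <- design$X[mask, , drop = FALSE]
    al <- drop_aliased(X)
    Xk <- X[, al$keep, drop = FALSE]
    core <- qp_irls(Xk, y, offset, maxit = maxit, tol = tol)
    p <- ncol(Xk)
    mu <- core$mu
    phi <- sum((y - mu)^2 / mu) / (n_used - p)
    V <- phi * chol2inv(chol(core$info))
    dimnames(V) <- list(colnames(Xk), colnames(Xk))
    beta <- stats::setNames(core$coefficients, colnames(Xk))
    term_index <- remap_terms(design$term_index, colnames(design$X), colnames(Xk))
    stratum_coef <- beta[grep("^stratum", names(beta))]
  } else {
    cf <- conditional_fit(design$Z[mask, , drop = FALSE], y, offset,
                          droplevels(design$stratum[mask]),
                          maxit = maxit, tol = tol)
    beta <- cf$beta; V <- cf$vcov_unscaled; mu <- cf$mu
    p <- length(beta) + cf$n_strata
    phi <- sum((y - mu)^2 / mu) / (n_used - p)
    V <- phi * V
    term_index <- remap_terms(design$term_index, colnames(design$X), names(beta))
    al <- list(dropped = cf$dropped)
    stratum_coef <- cf$lambda
  }
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  fit <- structure(list(coefficients = beta, vcov = V, dispersion = phi,
                        loglik = ll, n_used = n_used, p = p,
                        fitted = mu, y = y,
                        term_index = term_index, dropped = al$dropped,
                        stratum_coef = stratum_coef, method = method,
                        crossbases = design$crossbases,
                        subgroup = design$subgroup),
                   class = "qp_fit")
  fit$qaic <- qaic(fit)
  fit
}

# Map term -> column indices from the full design onto the kept coefficients.
remap_terms <- function(term_index, full_names, kept_names) {
  lapply(term_index, function(idx) {
    m <- match(full_names[idx], kept_names)
    m[!is.na(m)]
  })
}

# Conditional (stratum-absorbed) quasi-Poisson Newton iteration.
conditional_fit <- function(Z, y, offset, stratum, maxit = 100, tol = 1e-10) {
  s <- as.integer(stratum)
  ns <- max(s)
  al <- drop_aliased(center_by(Z, s, rep(1, length(y))))
  Zk <- Z[, al$keep, drop = FALSE]
  beta <- numeric(ncol(Zk))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta0 <- offset + drop(Zk %*% beta)
    # closed-form profiled stratum effects: match stratum totals
    lambda <- as.numeric(log(tapply(y, s, sum) / tapply(exp(eta0), s, sum)))
    eta <- eta0 + lambda[s]
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    Zt <- center_by(Zk, s, mu)
    step <- solve(crossprod(Zt * sqrt(mu)), drop(crossprod(Zt, y - mu)))
    beta <- beta + step
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1) &&
        max(abs(step)) < 1e-8) break
    dev_old <- dev
    if (it == maxit) stop("conditional fit did not converge in ", maxit,
                          " iterations (last deviance ", format(dev), ")")
  }
  eta0 <- offset + drop(Zk %*% beta)
  lambda <- as.numeric(log(tapply(y, s, sum) / tapply(exp(eta0), s, sum)))
  mu <- exp(eta0 + lambda[s])
  Zt <- center_by(Zk, s, mu)
  Vu <- chol2inv(chol(crossprod(Zt * sqrt(mu))))
  dimnames(Vu) <- list(colnames(Zk), colnames(Zk))
  list(beta = stats::setNames(beta, colnames(Zk)), vcov_unscaled = Vu,
       mu = mu, n_strata = ns, dropped = al$dropped,
       lambda = stats::setNames(as.numeric(lambda), levels(stratum)))
}

# Subtract weighted within-stratum means from each column.
center_by <- function(M, s, w) {
  wsum <- tapply(w, s, sum)
  means <- apply(M, 2, function(col) tapply(col * w, s, sum) / wsum)
  M - means[s, , drop = FALSE]
}

#' Q-AIC of a quasi-Poisson fit
#'
#' `QAIC = -2 * loglik / phi + 2 * p`, the quasi-likelihood analogue of AIC;
#' lower is better. When comparing nested candidates, supply the dispersion
#' of the most complex candidate as `dispersion` so all models are penalised
#' on the same scale.
#'
#' @param fit a `qp_fit`. @param dispersion dispersion used for the rescaling
#'   (defaults to the fit's own Pearson estimate).
#' @export
qaic <- function(fit, dispersion = fit$dispersion) {
  -2 * fit$loglik / dispersion + 2 * fit$p
}

#' Extract a model term's coefficients or covariance block
#'
#' @param fit a `qp_fit`. @param term model term name (e.g. a pollutant).
#' @export
term_coef <- function(fit, term) {
  idx <- fit$term_index[[term]]
  if (is.null(idx)) stop("no term '", term, "' in the fit")
  fit$coefficients[idx]
}

#' @rdname term_coef
#' @export
term_vcov <- function(fit, term) {
  idx <- fit$term_index[[term]]
  if (is.null(idx)) stop("no term '", term, "' in the fit")
  fit$vcov[idx, idx, drop = FALSE]
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("quasi-Poisson case-crossover fit (", x$method, " strata)\n", sep = "")
  cat("  n =", x$n_used, " p =", x$p,
      " dispersion =", format(x$dispersion, digits = 4),
      " QAIC =", format(x$qaic, digits = 6), "\n")
  if (length(x$dropped))
    cat("  dropped aliased columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a fit summary as CSV (term, estimate, SE, z)
#'
#' @param fit a `qp_fit`. @param path output file.
#' @export
write_fit_summary <- function(fit, path) {
  se <- sqrt(diag(fit$vcov))
  utils::write.csv(data.frame(term = names(fit$coefficients),
                              estimate = fit$coefficients, se = se,
                              z = fit$coefficients / se),
                   path, row.names = FALSE)
  invisible(path)
}
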