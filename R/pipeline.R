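# Study orchestration: descriptives, correlations, single-pollutant screen,
# multi-pollutant model selection under the collinearity rule, subgroup and
# sensitivity analyses, and the end-to-end report bundle.

#' Descriptive statistics table
#'
#' Mean, SD, min, the percentiles P1-P99, max and IQR (= P75 - P25) for each
#' numeric variable, with percentiles by linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param series a `daily_series` or data frame.
#' @param variables columns to describe; defaults to every numeric column
#'   except `population` and `holiday`.
#' @return data frame with one row per variable.
#' @export
describe_series <- function(series, variables = NULL) {
  if (is.null(variables)) {
    num <- vapply(series, is.numeric, TRUE)
    variables <- setdiff(names(series)[num], c("population", "holiday"))
  }
  rows <- lapply(variables, function(v) {
    x <- series[[v]]
    if (!is.numeric(x)) stop("non-numeric column: ", v)
    q <- stats::quantile(x, probs = c(.01, .05, .10, .25, .50, .75, .90,
                                      .95, .99), type = 7, names = FALSE)
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x), min = min(x),
               p1 = q[1], p5 = q[2], p10 = q[3], p25 = q[4], p50 = q[5],
               p75 = q[6], p90 = q[7], p95 = q[8], p99 = q[9], max = max(x),
               iqr = q[6] - q[4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix
#'
#' Rank-based correlation with average ranks for ties; symmetric with unit
#' diagonal. Constant columns yield `NA` entries and are reported in the
#' `flagged` attribute.
#'
#' @param series data frame. @param variables columns to correlate.
#' @export
spearman_matrix <- function(series, variables) {
  if (nrow(series) < 3) stop("need at least 3 rows")
  M <- as.matrix(series[, variables, drop = FALSE])
  const <- apply(M, 2, function(x) diff(range(x)) == 0)
  R <- suppressWarnings(stats::cor(M, method = "spearman"))
  diag(R) <- 1
  if (any(const)) {
    R[const, ] <- NA; R[, const] <- NA
    diag(R) <- ifelse(const, NA, 1)
    warning("constant column(s) flagged: ",
            paste(variables[const], collapse = ", "))
  }
  attr(R, "flagged") <- variables[const]
  R
}

#' Fit one study model (pollutant set + meteorology + holiday + strata)
#'
#' The workhorse behind the screen, subgroup and sensitivity analyses: builds
#' cross-bases for the requested pollutants (df 3 x 3, maxlag 14 by default)
#' and for temperature and humidity (df 3 x 3, maxlag 3), assembles the
#' year-month stratum design with the population offset and holiday term, and
#' fits the quasi-Poisson model.
#'
#' @param series a `daily_series`.
#' @param pollutants pollutant column names entering the model together.
#' @param subgroup response count column.
#' @param df_var,df_lag,maxlag cross-basis parameters for the pollutants.
#' @param met_df_var,met_df_lag,met_maxlag cross-basis parameters for
#'   temperature and humidity.
#' @param method stratum handling passed to [fit_quasipoisson()].
#' @param stratum_by passed to [build_design()].
#' @return list with the `fit` (`qp_fit`) and the pollutant `cbs`.
#' @export
fit_study_model <- function(series, pollutants, subgroup = "total",
                            df_var = 3, df_lag = 3, maxlag = 14,
                            met_df_var = 3, met_df_lag = 3, met_maxlag = 3,
                            method = "indicator",
                            stratum_by = "year_month") {
  miss <- setdiff(pollutants, names(series))
  if (length(miss))
    stop("missing pollutant column(s): ", paste(miss, collapse = ", "))
  cbs <- stats::setNames(lapply(pollutants, function(p)
    build_cross_basis(series[[p]], df_var = df_var, df_lag = df_lag,
                      maxlag = maxlag, series_id = p)), pollutants)
  met <- list(
    temperature = build_cross_basis(series$temperature, df_var = met_df_var,
                                    df_lag = met_df_lag, maxlag = met_maxlag,
                                    series_id = "temperature"),
    humidity = build_cross_basis(series$humidity, df_var = met_df_var,
                                 df_lag = met_df_lag, maxlag = met_maxlag,
                                 series_id = "humidity"))
  design <- build_design(series, c(cbs, met), subgroup = subgroup,
                         stratum_by = stratum_by)
  list(fit = fit_quasipoisson(design, method = method), cbs = cbs)
}

#' Single-pollutant screening
#'
#' Fits each pollutant in its own model and asks whether any extreme-contrast
#' cell (1st or 99th percentile vs median, over the standard lag windows) has
#' a 95% CI excluding 1 — the operational definition of a "significant
#' single-pollutant association" used to admit pollutants to multi-pollutant
#' models.
#'
#' @inheritParams fit_study_model
#' @param pollutants candidate pollutant columns.
#' @param windows lag windows for the extreme table.
#' @return data frame: `pollutant`, `significant`, `qaic`, plus the per-
#'   pollutant extreme tables in the `tables` attribute.
#' @export
screen_single_pollutants <- function(series, pollutants, windows = NULL, ...) {
  tabs <- list()
  rows <- lapply(pollutants, function(p) {
    m <- fit_study_model(series, p, ...)
    tab <- extreme_influence_table(list(total = m$fit), m$cbs,
                                   windows = windows)
    tabs[[p]] <<- tab
    data.frame(pollutant = p,
               significant = any(tab$lo > 1 | tab$hi < 1),
               qaic = m$fit$qaic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tabs
  out
}

#' Multi-pollutant model selection under the collinearity rule
#'
#' Builds the model plan: (i) pollutants without a significant
#' single-pollutant association are dropped; (ii) all pairs of the remaining
#' pollutants are enumerated; (iii) pairs whose Spearman correlation exceeds
#' the threshold are excluded; (iv) candidates are ranked by Q-AIC when pair
#' Q-AIC values are supplied, and each retained pollutant is assigned its
#' best available reporting model (best pair, else its single model).
#'
#' @param corr symmetric Spearman correlation matrix over the pollutants.
#' @param screen output of [screen_single_pollutants()], or any data frame
#'   with `pollutant`, `significant` and (optionally) `qaic` columns.
#' @param threshold collinearity cutoff on |r| (default 0.60).
#' @param pair_qaic optional named numeric vector of Q-AIC values for pairs,
#'   named `"A+B"` in sorted-name order.
#' @return list of class `model_plan`: `candidates` (list of pollutant sets),
#'   `excluded` (data frame with reasons), `reporting` (named list,
#'   pollutant -> pollutant set of its reporting model).
#' @export
select_models <- function(corr, screen, threshold = 0.60, pair_qaic = NULL) {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("'corr' must be symmetric")
  excluded <- data.frame(item = character(), reason = character(),
                         stringsAsFactors = FALSE)
  sig <- screen$pollutant[screen$significant]
  for (p in setdiff(screen$pollutant, sig))
    excluded <- rbind(excluded, data.frame(
      item = p, reason = "no significant single-pollutant association"))
  candidates <- lapply(sig, function(p) p)
  if (length(sig) >= 2) {
    pairs <- utils::combn(sort(sig), 2, simplify = FALSE)
    for (pr in pairs) {
      r <- corr[pr[1], pr[2]]
      if (is.na(r)) {
        excluded <- rbind(excluded, data.frame(
          item = paste(pr, collapse = "+"),
          reason = "correlation undefined"))
      } else if (abs(r) > threshold) {
        excluded <- rbind(excluded, data.frame(
          item = paste(pr, collapse = "+"),
          reason = sprintf("Spearman r = %.4f > %.2f", r, threshold)))
      } else {
        candidates[[length(candidates) + 1L]] <- pr
      }
    }
  }
  qaics <- vapply(candidates, function(set) {
    key <- paste(sort(set), collapse = "+")
    if (!is.null(pair_qaic) && key %in% names(pair_qaic)) pair_qaic[[key]]
    else if (length(set) == 1 && "qaic" %in% names(screen))
      screen$qaic[match(set, screen$pollutant)]
    else NA_real_
  }, numeric(1))
  reporting <- stats::setNames(vector("list", length(sig)), sig)
  for (p in sig) {
    holds <- which(vapply(candidates, function(set) p %in% set, TRUE))
    multi <- holds[vapply(candidates[holds], length, 1L) > 1]
    pick <- if (length(multi)) {
      if (all(is.na(qaics[multi]))) multi[1] else multi[which.min(qaics[multi])]
    } else holds[1]
    reporting[[p]] <- candidates[[pick]]
  }
  structure(list(candidates = candidates, qaic = qaics,
                 excluded = excluded, reporting = reporting,
                 threshold = threshold),
            class = "model_plan")
}

#' @export
print.model_plan <- function(x, ...) {
  cat("model plan (collinearity threshold |r| >", x$threshold, ")\n")
  for (i in seq_along(x$candidates))
    cat("  candidate:", paste(x$candidates[[i]], collapse = " + "),
        if (!is.na(x$qaic[i])) paste0("  QAIC ", format(x$qaic[i])), "\n")
  if (nrow(x$excluded))
    for (i in seq_len(nrow(x$excluded)))
      cat("  excluded:", x$excluded$item[i], "-", x$excluded$reason[i], "\n")
  invisible(x)
}

#' Subgroup (stratified) analysis
#'
#' Refits the identical reporting model with each population group's count
#' column as the response and tabulates the extreme influence per group, the
#' layout of the subgroup cumulative-influence tables.
#'
#' @inheritParams fit_study_model
#' @param pollutants pollutant set of the model (e.g. a reporting pair).
#' @param groups count columns to analyse.
#' @param windows lag windows for the tables.
#' @return list: `table` (combined `extreme_influence_table` across groups),
#'   `fits` (per-group `qp_fit`), `cbs`.
#' @export
stratified_analysis <- function(series, pollutants,
                                groups = c("total", "male", "female",
                                           "elderly", "adult"),
                                windows = NULL, ...) {
  fits <- list()
  cbs <- NULL
  for (g in groups) {
    if (!g %in% names(series)) stop("no count column '", g, "' in the series")
    if (all(series[[g]] == 0)) stop("subgroup '", g, "' has all-zero counts")
    m <- fit_study_model(series, pollutants, subgroup = g, ...)
    fits[[g]] <- m$fit
    cbs <- m$cbs
  }
  list(table = extreme_influence_table(fits, cbs, windows = windows),
       fits = fits, cbs = cbs)
}

#' Sensitivity scan over spline dimensions and maximum lag
#'
#' Re-runs the main model varying one modelling choice at a time: the
#' exposure-spline df over `df_var_grid`, the lag-spline df over
#' `df_lag_grid`, and the maximum pollutant lag over `maxlag_grid` (windows
#' truncated accordingly). Returns one extreme-influence table per grid
#' point plus a stability summary: the largest absolute change in cumulative
#' log-RR against the base analysis over the windows both share.
#'
#' @inheritParams fit_study_model
#' @param pollutants pollutant set of the base model.
#' @param df_var_grid,df_lag_grid,maxlag_grid grids scanned one at a time.
#' @param base named list with the base `df_var`, `df_lag`, `maxlag`.
#' @return list of class `sensitivity_scan`: `tables` (named by grid point),
#'   `stability` (data frame), `base_table`.
#' @export
sensitivity_scan <- function(series, pollutants,
                             df_var_grid = 2:6, df_lag_grid = 2:6,
                             maxlag_grid = 12:21,
                             base = list(df_var = 3, df_lag = 3, maxlag = 14),
                             ...) {
  run_point <- function(df_var, df_lag, maxlag) {
    m <- fit_study_model(series, pollutants, df_var = df_var,
                         df_lag = df_lag, maxlag = maxlag, ...)
    extreme_influence_table(list(total = m$fit), m$cbs)
  }
  base_tab <- run_point(base$df_var, base$df_lag, base$maxlag)
  pts <- unique(rbind(
    data.frame(df_var = df_var_grid, df_lag = base$df_lag, maxlag = base$maxlag),
    data.frame(df_var = base$df_var, df_lag = df_lag_grid, maxlag = base$maxlag),
    data.frame(df_var = base$df_var, df_lag = base$df_lag, maxlag = maxlag_grid)))
  tables <- list()
  stab <- list()
  for (i in seq_len(nrow(pts))) {
    key <- sprintf("df_var%d.df_lag%d.maxlag%d",
                   pts$df_var[i], pts$df_lag[i], pts$maxlag[i])
    tab <- tryCatch(run_point(pts$df_var[i], pts$df_lag[i], pts$maxlag[i]),
                    error = function(e) {
                      warning("grid point ", key, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(tab)) next
    tables[[key]] <- tab
    shared <- merge(base_tab, tab,
                    by = c("pollutant", "group", "block", "window"),
                    suffixes = c(".base", ".alt"))
    stab[[key]] <- data.frame(
      point = key, df_var = pts$df_var[i], df_lag = pts$df_lag[i],
      maxlag = pts$maxlag[i],
      max_abs_delta_log_rr = max(abs(shared$log_rr.alt - shared$log_rr.base)),
      stringsAsFactors = FALSE)
  }
  structure(list(tables = tables,
                 stability = do.call(rbind, stab),
                 base_table = base_tab, base = base),
            class = "sensitivity_scan")
}

#' Run the full study pipeline
#'
#' Simulate (or ingest and validate) the daily series, then: descriptives,
#' Spearman correlations, single-pollutant screen, multi-pollutant model
#' selection, per-group fits and extreme-influence tables, cumulative
#' exposure-response curves, and (optionally) the sensitivity scan. All
#' tables are written as CSV under `out_dir` together with a run log.
#'
#' @param config list with either `simulation` (a [sim_config()]) or
#'   `input_csv` (path, plus `pollutants` naming the pollutant columns);
#'   optional elements `groups`, `threshold`, `windows`, `sensitivity`
#'   (logical), and model parameters passed to [fit_study_model()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return list of class `study_report`: `series`, `descriptives`,
#'   `correlations`, `screen`, `plan`, `subgroup_tables`, `curves`,
#'   `sensitivity` (or `NULL`).
#' @export
run_study <- function(config, out_dir = NULL) {
  log_lines <- c(paste("lagrisk run,", format(Sys.time())),
                 paste("R", getRversion()))
  series <- if (!is.null(config$simulation)) {
    log_lines <- c(log_lines, paste("simulated series, seed",
                                    config$simulation$seed))
    generate_series(config$simulation)
  } else if (!is.null(config$input_csv)) {
    read_daily_series(config$input_csv, pollutants = config$pollutants)
  } else stop("config must name either 'simulation' or 'input_csv'")
  pollutants <- if (!is.null(config$pollutants)) config$pollutants else
    names(attr(series, "truth")$config$pollutants)
  miss <- setdiff(pollutants, names(series))
  if (length(miss))
    stop("missing pollutant column(s): ", paste(miss, collapse = ", "))
  groups <- config$groups %||% c("total", "male", "female", "elderly", "adult")
  threshold <- config$threshold %||% 0.60
  model_args <- config$model %||% list()

  desc <- describe_series(series)
  corr <- spearman_matrix(series, c(pollutants, "temperature", "humidity"))
  screen <- do.call(screen_single_pollutants,
                    c(list(series = series, pollutants = pollutants,
                           windows = config$windows), model_args))
  pair_sets <- if (sum(screen$significant) >= 2)
    utils::combn(sort(screen$pollutant[screen$significant]), 2,
                 simplify = FALSE) else list()
  pair_qaic <- numeric(0)
  for (pr in pair_sets) {
    r <- corr[pr[1], pr[2]]
    if (!is.na(r) && abs(r) <= threshold) {
      m <- do.call(fit_study_model,
                   c(list(series = series, pollutants = pr), model_args))
      pair_qaic[paste(pr, collapse = "+")] <- m$fit$qaic
    }
  }
  plan <- select_models(corr[pollutants, pollutants], screen,
                        threshold = threshold, pair_qaic = pair_qaic)

  subgroup_tables <- list()
  curves <- list()
  for (p in names(plan$reporting)) {
    set <- plan$reporting[[p]]
    sa <- do.call(stratified_analysis,
                  c(list(series = series, pollutants = set, groups = groups,
                         windows = config$windows), model_args))
    subgroup_tables[[p]] <- sa$table[sa$table$pollutant == p, ]
    cb <- sa$cbs[[p]]
    xobs <- cb$x[!cb$incomplete]
    grid <- seq(min(xobs), max(xobs), length.out = 50)
    curves[[p]] <- overall_curve(sa$fits$total %||% sa$fits[[1]], cb,
                                 grid = grid,
                                 ref = stats::quantile(xobs, 0.5, type = 7,
                                                       names = FALSE))
    log_lines <- c(log_lines,
                   paste0("reporting model for ", p, ": ",
                          paste(set, collapse = " + "),
                          " (QAIC path: see model_plan.csv)"))
  }
  sens <- NULL
  if (isTRUE(config$sensitivity) && length(plan$reporting)) {
    p1 <- names(plan$reporting)[1]
    sens <- do.call(sensitivity_scan,
                    c(list(series = series,
                           pollutants = plan$reporting[[p1]]),
                      config$sensitivity_grids %||% list(), model_args))
  }

  report <- structure(list(series = series, descriptives = desc,
                           correlations = corr, screen = screen, plan = plan,
                           subgroup_tables = subgroup_tables, curves = curves,
                           sensitivity = sens),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(round(corr, 4), file.path(out_dir, "correlations.csv"))
    utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
    plan_df <- data.frame(
      candidate = vapply(plan$candidates, paste, "", collapse = "+"),
      qaic = plan$qaic)
    utils::write.csv(plan_df, file.path(out_dir, "model_plan.csv"),
                     row.names = FALSE)
    for (p in names(subgroup_tables))
      write_effect_csv(subgroup_tables[[p]],
                       file.path(out_dir, paste0("extreme_", p, ".csv")))
    for (p in names(curves))
      write_effect_csv(curves[[p]],
                       file.path(out_dir, paste0("curve_", p, ".csv")),
                       digits = NULL)
    if (!is.null(sens))
      utils::write.csv(sens$stability,
                       file.path(out_dir, "sensitivity_stability.csv"),
                       row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
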