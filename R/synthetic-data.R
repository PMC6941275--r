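# Synthetic daily series generator with known ground-truth effect surfaces.
#
# The generator produces the data structure the case-crossover DLNM analysis
# assumes: seasonal, autocorrelated, mutually correlated pollutant series;
# meteorology in seasonal anti-phase with the pollutants; overdispersed daily
# event counts driven by a known non-linear lagged log-RR surface, a seasonal
# baseline, a holiday effect and a population offset.

#' Piecewise-linear effect surface specification
#'
#' The exposure-response function of the ground truth is a hinge ("J": zero up
#' to `threshold_high`, then linear with `slope_high`) or a "V" (additionally
#' rising below `threshold_low` with `slope_low`); `shape = "null"` is
#' identically zero. The lag structure distributes the effect over lags
#' `0..L` with nonnegative weights summing to 1.
#'
#' @param shape one of `"null"`, `"J"`, `"V"`.
#' @param threshold_high,slope_high hinge location and slope (log-RR per unit
#'   exposure) of the rising arm.
#' @param threshold_low,slope_low location and slope of the low-exposure arm
#'   (V shape only; risk increases as exposure falls below `threshold_low`).
#' @param lag_weights nonnegative weights over lags `0..L`, summing to 1.
#' @export
effect_surface <- function(shape = c("null", "J", "V"),
                           threshold_high = NA, slope_high = NA,
                           threshold_low = NA, slope_low = NA,
                           lag_weights = rep(1 / 15, 15)) {
  shape <- match.arg(shape)
  if (shape != "null") {
    if (abs(sum(lag_weights) - 1) > 1e-12)
      stop("'lag_weights' must sum to 1")
    if (any(lag_weights < 0)) stop("'lag_weights' must be nonnegative")
    if (!is.finite(threshold_high) || !is.finite(slope_high))
      stop("'threshold_high' and 'slope_high' are required")
    if (shape == "V") {
      if (!is.finite(threshold_low) || !is.finite(slope_low))
        stop("V shape needs 'threshold_low' and 'slope_low'")
      if (threshold_low > threshold_high)
        stop("'threshold_low' must not exceed 'threshold_high'")
    }
  }
  structure(list(shape = shape,
                 threshold_high = threshold_high, slope_high = slope_high,
                 threshold_low = threshold_low, slope_low = slope_low,
                 lag_weights = lag_weights),
            class = "effect_surface")
}

# Exposure-response function f(x) of an effect surface, vectorised.
surface_fx <- function(eff, x) {
  if (is.null(eff) || eff$shape == "null") return(rep(0, length(x)))
  out <- eff$slope_high * pmax(x - eff$threshold_high, 0)
  if (eff$shape == "V")
    out <- out + eff$slope_low * pmax(eff$threshold_low - x, 0)
  out
}

#' Pollutant series specification
#'
#' One pollutant's daily concentration is generated on the log scale, the
#' natural scale for concentration data (right-skewed marginals, as observed
#' monitoring series are):
#' `x_t = max(mean * exp(seasonal cosine + loading * shared factor + AR(1)
#' noise), 0.1)`, so `mean` is (approximately) the median concentration in
#' micrograms per cubic metre while `seasonal_amplitude`, the factor loading
#' and `noise_sd` are dimensionless log-scale quantities. The shared latent
#' daily factor (standard normal, common to all pollutants) induces the
#' positive cross-pollutant correlation seen in urban monitoring data, and
#' the seasonal cosine peaks at `peak_doy` (day-of-year; pollutants typically
#' peak in winter, driving their negative correlation with temperature). The
#' 0.1 floor keeps concentrations physical and the spline range finite; with
#' the log-scale formulation it essentially never binds.
#'
#' @param name pollutant label (becomes the series column name).
#' @param mean median concentration (micrograms per cubic metre).
#' @param seasonal_amplitude amplitude of the annual cosine (log scale).
#' @param ar_coefficient AR(1) coefficient of the noise, `|ar| < 1`.
#' @param noise_sd innovation standard deviation (log scale), `> 0`.
#' @param shared_factor_loading loading on the common daily factor (log
#'   scale).
#' @param peak_doy day-of-year at which the seasonal cosine peaks.
#' @param effect an [effect_surface()], or `NULL` for a null pollutant.
#' @export
pollutant_spec <- function(name, mean, seasonal_amplitude, ar_coefficient,
                           noise_sd, shared_factor_loading = 0,
                           peak_doy = 15, effect = NULL) {
  if (abs(ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (!is.null(effect) && !inherits(effect, "effect_surface"))
    stop("'effect' must be an effect_surface or NULL")
  structure(list(name = name, mean = mean,
                 seasonal_amplitude = seasonal_amplitude,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 shared_factor_loading = shared_factor_loading,
                 peak_doy = peak_doy, effect = effect),
            class = "pollutant_spec")
}

#' Seasonal meteorological series parameters
#'
#' @param mean annual mean; @param seasonal_amplitude annual cosine amplitude;
#' @param ar_coefficient AR(1) coefficient; @param noise_sd innovation SD;
#' @param peak_doy day-of-year of the seasonal peak (mid-July for temperature
#'   in the northern hemisphere).
#' @export
met_spec <- function(mean, seasonal_amplitude, ar_coefficient, noise_sd,
                     peak_doy = 197) {
  if (abs(ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  list(mean = mean, seasonal_amplitude = seasonal_amplitude,
       ar_coefficient = ar_coefficient, noise_sd = noise_sd,
       peak_doy = peak_doy)
}

#' Simulation configuration
#'
#' Bundles every parameter of the generator. Counts are drawn with mean
#' `mu_t = Population_ye * exp(baseline + seasonal baseline + sum_i
#' sum_l f_i(x_{i,t-l}) w_i(l) + holiday effect)` and variance
#' `dispersion * mu_t` (negative binomial; Poisson when `dispersion = 1`).
#'
#' @param start_date first calendar day (Date or ISO string).
#' @param n_days number of consecutive days (`>= 366`).
#' @param seed integer seed; the series is a deterministic function of the
#'   configuration including the seed.
#' @param pollutants list of [pollutant_spec()] objects.
#' @param temp_spec,rh_spec [met_spec()] parameters for temperature (deg C)
#'   and relative humidity (%, clamped to [0, 100]).
#' @param baseline_log_rate log cases per person-day at reference conditions.
#' @param baseline_seasonal_amplitude amplitude of the seasonal term in the
#'   log rate (peaks in winter, confounding the pollutant effects so the
#'   stratum terms have real work to do).
#' @param dispersion variance/mean ratio of the count draw, `>= 1`.
#' @param holiday_effect log-rate shift on public holidays.
#' @param population_by_year named vector, year -> year-end population.
#' @param holiday_doys days-of-year flagged as public holidays every year.
#' @param male_prob,elderly_prob binomial thinning probabilities for the
#'   gender and age subgroup splits of the total count.
#' @export
sim_config <- function(start_date = "2008-01-01", n_days = 2557L,
                       seed = 1L, pollutants,
                       temp_spec = met_spec(23, 6.5, 0.9, 1.1),
                       rh_spec = met_spec(73, 8, 0.85, 4.5),
                       baseline_log_rate = log(25 / 1e7),
                       baseline_seasonal_amplitude = 0.15,
                       dispersion = 3,
                       holiday_effect = -0.05,
                       population_by_year = NULL,
                       holiday_doys = c(1:3, 121:123, 274:280),
                       male_prob = 0.595, elderly_prob = 0.484) {
  start_date <- as.Date(start_date)
  n_days <- as.integer(n_days)
  if (n_days < 366L) stop("'n_days' must be at least 366")
  if (dispersion < 1) stop("'dispersion' must be >= 1")
  if (!length(pollutants)) stop("at least one pollutant_spec is required")
  if (inherits(pollutants, "pollutant_spec")) pollutants <- list(pollutants)
  names(pollutants) <- vapply(pollutants, `[[`, "", "name")
  dates <- seq(start_date, by = "day", length.out = n_days)
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  if (is.null(population_by_year))
    population_by_year <- stats::setNames(rep(1e7, length(years)),
                                          as.character(years))
  missing_y <- setdiff(as.character(years), names(population_by_year))
  if (length(missing_y))
    stop("no population entry for year(s): ",
         paste(missing_y, collapse = ", "))
  burn <- max(c(0L, vapply(pollutants, function(p)
    if (is.null(p$effect) || p$effect$shape == "null") 0L
    else length(p$effect$lag_weights) - 1L, 0L)))
  if (n_days < burn + 28L)
    stop("'n_days' must exceed the effect burn-in plus one stratum")
  structure(list(start_date = start_date, n_days = n_days, seed = as.integer(seed),
                 pollutants = pollutants, temp_spec = temp_spec,
                 rh_spec = rh_spec,
                 baseline_log_rate = baseline_log_rate,
                 baseline_seasonal_amplitude = baseline_seasonal_amplitude,
                 dispersion = dispersion, holiday_effect = holiday_effect,
                 population_by_year = population_by_year,
                 holiday_doys = as.integer(holiday_doys),
                 male_prob = male_prob, elderly_prob = elderly_prob,
                 burn_in = burn),
            class = "sim_config")
}

#' Default five-pollutant study configuration
#'
#' Emulates a seven-year subtropical-city monitoring record: SO2, NO2 and
#' PM10 with J-shaped (threshold) risk surfaces and strong mutual
#' correlation, CO as a null pollutant, O3 with a V-shaped surface and weak
#' coupling to the others, temperature and humidity peaking in summer while
#' the pollutants peak in winter. Daily counts average about 25 with
#' variance/mean 3.
#'
#' @param seed integer seed.
#' @param n_days series length in days (default seven years).
#' @export
default_sim_config <- function(seed = 1L, n_days = 2557L) {
  unif15 <- rep(1 / 15, 15)
  sim_config(
    seed = seed, n_days = n_days,
    pollutants = list(
      pollutant_spec("SO2", 12, 0.35, 0.85, 0.14, shared_factor_loading = 0.28,
                     effect = effect_surface("J", threshold_high = 16,
                                             slope_high = 0.008,
                                             lag_weights = unif15)),
      pollutant_spec("NO2", 41, 0.30, 0.80, 0.13, shared_factor_loading = 0.28,
                     effect = effect_surface("J", threshold_high = 70,
                                             slope_high = 0.004,
                                             lag_weights = unif15)),
      pollutant_spec("PM10", 48, 0.40, 0.85, 0.16, shared_factor_loading = 0.32,
                     effect = effect_surface("J", threshold_high = 90,
                                             slope_high = 0.002,
                                             lag_weights = unif15)),
      pollutant_spec("CO", 1.1, 0.25, 0.80, 0.16, shared_factor_loading = 0.12),
      pollutant_spec("O3", 50, 0.30, 0.80, 0.17, shared_factor_loading = 0.10,
                     peak_doy = 280,
                     effect = effect_surface("V", threshold_high = 75,
                                             slope_high = 0.003,
                                             threshold_low = 35,
                                             slope_low = 0.006,
                                             lag_weights = unif15))))
}

#' Calibration and recovery study configurations
#'
#' `null_sim_config()` is the dispersion-calibration / type-I-error setting:
#' a single pollutant with no effect on the counts, Poisson counts
#' (`dispersion = 1`), six years of data. Any association the analysis finds
#' is spurious, so the 95% CI for the 99th-vs-median cumulative RR should
#' exclude 1 about 5% of the time and the Pearson dispersion should sit near
#' 1.
#'
#' `recovery_sim_config()` is the parameter-recovery setting: a single
#' pollutant with a J-shaped surface (hinge at 16, near the series' 75th
#' percentile; slope 0.026 per unit) and uniform lag weights over lags 0-14,
#' sized so the true cumulative log-RR of the 99th-vs-median contrast over
#' lag 0-12 is about 0.4 (RR about 1.5, the magnitude of headline effects in
#' this literature), with overdispersed counts (`dispersion = 2`).
#'
#' @param seed integer seed. @param n_days series length.
#' @export
null_sim_config <- function(seed = 1L, n_days = 2192L) {
  sim_config(
    seed = seed, n_days = n_days, dispersion = 1,
    pollutants = list(
      pollutant_spec("SO2", 12, 0.35, 0.85, 0.14,
                     shared_factor_loading = 0.28)))
}

#' @rdname null_sim_config
#' @export
recovery_sim_config <- function(seed = 1L, n_days = 2557L) {
  sim_config(
    seed = seed, n_days = n_days, dispersion = 2,
    pollutants = list(
      pollutant_spec("SO2", 12, 0.35, 0.85, 0.14,
                     shared_factor_loading = 0.28,
                     effect = effect_surface("J", threshold_high = 16,
                                             slope_high = 0.026,
                                             lag_weights = rep(1 / 15, 15)))))
}

# One seasonal AR(1) latent series of length n (stationary initialisation).
seasonal_ar1 <- function(n, doy, spec, shock = 0) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, spec$noise_sd / sqrt(1 - spec$ar_coefficient^2))
  eps <- stats::rnorm(n - 1, 0, spec$noise_sd)
  for (t in 2:n) z[t] <- spec$ar_coefficient * z[t - 1] + eps[t - 1]
  spec$mean +
    spec$seasonal_amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365.25) +
    shock + z
}

#' Generate a synthetic daily series
#'
#' Simulates exposures over `burn_in + n_days` days (the burn-in precedes
#' `start_date` so every retained day has a complete lag history), computes
#' the true daily mean `mu_t` from the configured effect surfaces, and draws
#' overdispersed counts. Subgroup counts are independent binomial splits of
#' the total (male/female and elderly/adult), so the pairs sum to the total
#' on every row.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `daily_series` with columns `date`,
#'   `total`, `male`, `female`, `elderly`, `adult`, one column per pollutant,
#'   `temperature`, `humidity`, `holiday`, `population`. The attribute
#'   `truth` records the true `mu`, the linear predictor, the burn-in
#'   exposure history and the configuration, for parameter-recovery studies.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  burn <- config$burn_in
  n <- config$n_days
  n_ext <- n + burn
  dates_ext <- seq(config$start_date - burn, by = "day", length.out = n_ext)
  doy <- as.integer(format(dates_ext, "%j"))
  dates <- dates_ext[(burn + 1L):n_ext]

  shared <- stats::rnorm(n_ext)
  poll_ext <- sapply(config$pollutants, function(p) {
    p0 <- p; p0$mean <- 0
    g <- seasonal_ar1(n_ext, doy, p0,
                      shock = p$shared_factor_loading * shared)
    pmax(p$mean * exp(g), 0.1)
  })
  temperature <- seasonal_ar1(n_ext, doy, config$temp_spec)[(burn + 1L):n_ext]
  humidity <- pmin(pmax(
    seasonal_ar1(n_ext, doy, config$rh_spec)[(burn + 1L):n_ext], 0), 100)

  holiday <- as.integer(as.integer(format(dates, "%j")) %in% config$holiday_doys)
  year_chr <- format(dates, "%Y")
  population <- unname(config$population_by_year[year_chr])

  # True linear predictor: per-pollutant lagged surface contributions.
  eta <- config$baseline_log_rate +
    config$baseline_seasonal_amplitude *
      cos(2 * pi * (as.integer(format(dates, "%j")) - 15) / 365.25) +
    config$holiday_effect * holiday
  for (p in config$pollutants) {
    if (is.null(p$effect) || p$effect$shape == "null") next
    w <- p$effect$lag_weights
    fx <- surface_fx(p$effect, poll_ext[, p$name])
    contrib <- numeric(n)
    for (l in seq_along(w) - 1L)
      contrib <- contrib + w[l + 1L] * fx[(burn + 1L - l):(n_ext - l)]
    eta <- eta + contrib
  }
  mu <- population * exp(eta)

  total <- if (config$dispersion == 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (config$dispersion - 1))
  }
  male <- stats::rbinom(n, total, config$male_prob)
  elderly <- stats::rbinom(n, total, config$elderly_prob)

  out <- data.frame(date = dates, total = total, male = male,
                    female = total - male, elderly = elderly,
                    adult = total - elderly,
                    poll_ext[(burn + 1L):n_ext, , drop = FALSE],
                    temperature = temperature, humidity = humidity,
                    holiday = holiday, population = population,
                    check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("daily_series", "data.frame")
  attr(out, "truth") <- list(mu = mu, eta = eta,
                             exposures_ext = poll_ext, burn_in = burn,
                             config = config)
  out
}

#' True cumulative log relative risk of the generator
#'
#' The ground-truth analogue of the fitted cumulative contrast: for a
#' pollutant with effect surface `f` and lag weights `w`,
#' `sum_{l = l0..l1} (f(at) - f(ref)) * w(l)`, in exact arithmetic.
#'
#' @param config a [sim_config()].
#' @param pollutant pollutant name (must carry a non-null effect surface).
#' @param at,ref exposure values to contrast.
#' @param window integer pair `c(l0, l1)` within `0..L`.
#' @return the true cumulative log-RR (a scalar).
#' @export
true_cumulative_log_rr <- function(config, pollutant, at, ref,
                                   window = c(0, 14)) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$pollutants[[pollutant]]
  if (is.null(p)) stop("unknown pollutant: ", pollutant)
  eff <- p$effect
  if (is.null(eff) || eff$shape == "null")
    stop("pollutant '", pollutant, "' has no effect surface")
  L <- length(eff$lag_weights) - 1L
  if (window[1] < 0 || window[2] > L || window[1] > window[2])
    stop("window outside 0..", L)
  (surface_fx(eff, at) - surface_fx(eff, ref)) *
    sum(eff$lag_weights[(window[1] + 1L):(window[2] + 1L)])
}

#' Write / read a daily series as CSV
#'
#' ISO-8601 date column, one column per field. `read_daily_series` validates
#' the schema: required columns present, dates strictly consecutive.
#'
#' @param series a `daily_series`. @param path file path.
#' @export
write_daily_series <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_series
#' @param pollutants pollutant column names expected in the file.
#' @export
read_daily_series <- function(path, pollutants = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  validate_daily_series(df, pollutants = pollutants)
}

#' Validate a daily series table
#'
#' Checks the analysis-dataset contract: required columns present, dates
#' strictly consecutive with no gaps, pollutant concentrations positive,
#' humidity within 0-100. Gaps are an error, never silently imputed.
#'
#' @param df a data frame with at least `date`, `total`, `holiday`,
#'   `population` columns.
#' @param pollutants pollutant columns that must be present (optional).
#' @return the validated data frame with class `daily_series`.
#' @export
validate_daily_series <- function(df, pollutants = NULL) {
  required <- c("date", "total", "holiday", "population", pollutants)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("daily series is missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(df$date, "Date")) df$date <- as.Date(df$date)
  d <- diff(as.integer(df$date))
  if (any(d != 1L))
    stop("dates must be strictly consecutive days; first gap after ",
         format(df$date[which(d != 1L)[1]]))
  if (!is.null(pollutants))
    for (p in pollutants)
      if (any(df[[p]] <= 0)) stop("non-positive values in pollutant ", p)
  if ("humidity" %in% names(df) &&
      (any(df$humidity < 0) || any(df$humidity > 100)))
    stop("humidity must lie in [0, 100]")
  class(df) <- unique(c("daily_series", class(df)))
  df
}
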