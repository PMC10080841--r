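#' Environmental variable names of a daily panel
#'
#' The ten environmental columns of a daily admissions panel, in canonical
#' order: fine particulate matter (pm25), inhalable particulate matter (pm10),
#' coarse particulate matter (pmc = pm10 - pm25), sulfur dioxide (so2),
#' nitrogen dioxide (no2), carbon monoxide (co), ozone (o3), the air quality
#' index (aqi), daily mean temperature (tem) and relative humidity (rh).
#'
#' @return Character vector of length 10.
#' @export
env_variables <- function() {
  c("pm25", "pm10", "pmc", "so2", "no2", "co", "o3", "aqi", "tem", "rh")
}

# Calibration constants for the synthetic environmental series: long-run mean
# and SD per variable (units: ug/m3 for pollutants except CO in mg/m3, degrees
# C for tem, % for rh), seasonal amplitude (in SD units) and day-of-year of
# the seasonal peak.  Pollutants peak in winter, ozone and temperature in
# summer.
env_calibration <- function() {
  data.frame(
    variable = c("pm25", "pm10", "pmc", "so2", "no2", "co", "o3", "aqi",
                 "tem", "rh"),
    mean = c(57.9, 95.7, 37.8, 12.7, 53.9, 1.0, 96.6, 85.2, 16.9, 80.5),
    sd   = c(40.6, 62.1, 25.6, 5.5, 17.7, 0.4, 54.6, 48.5, 7.3, 9.2),
    season_amp  = c(0.9, 0.9, 0.8, 0.8, 0.7, 0.8, 1.0, 0.8, 1.25, 0.4),
    season_peak = c(15, 15, 15, 15, 15, 15, 196, 15, 196, 258),
    stringsAsFactors = FALSE
  )
}

# Reference scales used to fold the pollutant columns into a single
# deterministic, monotone air-quality index:
# aqi = 100 * max_P(concentration_P / reference_P).
aqi_reference <- function() {
  c(pm25 = 75, pm10 = 150, so2 = 150, no2 = 80, co = 4, o3 = 160)
}

#' Default synthetic holiday calendar
#'
#' Recurring public holidays for the synthetic panel: January 1--3, the first
#' week of October, plus one seven-day movable block per year (emulating a
#' lunar-calendar festival) whose start day, between January 22 and
#' February 12, is chosen deterministically from \code{seed} and the year.
#'
#' @param years Integer vector of calendar years to cover.
#' @param seed Integer seed for the movable block (fixed by default so the
#'   calendar is identical across generator seeds).
#' @return Sorted \code{Date} vector of holidays.
#' @export
default_holidays <- function(years, seed = 1L) {
  out <- as.Date(character(0))
  for (y in sort(unique(as.integer(years)))) {
    fixed <- c(
      seq(as.Date(sprintf("%d-01-01", y)), by = "day", length.out = 3),
      seq(as.Date(sprintf("%d-10-01", y)), by = "day", length.out = 7)
    )
    offset <- derive_seed(seed, y) %% 22L  # 0..21 days past Jan 22
    movable <- seq(as.Date(sprintf("%d-01-22", y)) + offset,
                   by = "day", length.out = 7)
    out <- c(out, fixed, movable)
  }
  sort(unique(out))
}

#' Configuration for the synthetic daily-panel generator
#'
#' Builds and validates the parameter set of [generate_panel()].  All effects
#' act on the log scale of the expected daily admission count:
#' \code{log E\[count\] = log(baseline_level) + yearly_trend * years_elapsed +
#' annual harmonic + weekly effect + holiday effect + lagged environmental
#' effects on standardized covariates}.
#'
#' @param start_date First calendar day (ISO string or \code{Date}).
#' @param n_days Number of consecutive days (default 1461, four years).
#' @param baseline_level Expected count at the start, before seasonal and
#'   environmental effects (default 50; with the default rising trend this
#'   yields a four-year mean near 70 with SD near 33).
#' @param yearly_trend Multiplicative growth per year, log scale.
#' @param annual_amplitude Amplitude of the annual harmonic, log scale.
#' @param weekly_effects Length-7 numeric, Monday first, log scale (admissions
#'   dip at weekends by default).
#' @param holiday_effect Log-scale effect on holidays.
#' @param env_effect_coeffs Named list, variable -> numeric vector of per-lag
#'   coefficients (lags 1..L, log scale), applied to the variable standardized
#'   with its configured mean and SD.
#' @param dispersion Positive real (negative-binomial size; daily counts are
#'   overdispersed, SD 35 >> sqrt(70)), or \code{"poisson"}, or \code{"none"}
#'   for the deterministic variance-0 mode (counts = rounded intensity).
#' @param env_means,env_sds Named numeric vectors overriding the per-variable
#'   calibration constants.
#' @param env_noise Logical; \code{FALSE} freezes the environmental series at
#'   their deterministic seasonal curves.
#' @param missing_rate Fraction of days whose environmental cells are blanked
#'   by [inject_missing()] (applied by [generate_panel()] when > 0).
#' @param holidays Optional \code{Date} vector; default [default_holidays()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class \code{ha_generator_config}.
#' @export
generator_config <- function(start_date = "2015-01-01",
                             n_days = 1461L,
                             baseline_level = 49,
                             yearly_trend = 0.15,
                             annual_amplitude = 0.45,
                             weekly_effects = c(0.08, 0.06, 0.05, 0.03,
                                                0.02, -0.15, -0.18),
                             holiday_effect = -0.25,
                             env_effect_coeffs = list(
                               tem  = c(0.040, 0.030, 0.020, 0.000, 0.020, 0.000),
                               rh   = c(-0.010, 0, 0, 0, 0, 0),
                               pm25 = c(0.015, 0.010, 0.010, 0, 0, 0),
                               o3   = c(0.015, 0.010, 0, 0, 0, 0),
                               no2  = c(0.010, 0, 0, 0, 0, 0),
                               co   = c(0.010, 0, 0, 0, 0, 0)
                             ),
                             dispersion = 50,
                             env_means = NULL,
                             env_sds = NULL,
                             env_noise = TRUE,
                             missing_rate = 0,
                             holidays = NULL,
                             seed = 42L) {
  cal <- env_calibration()
  means <- stats::setNames(cal$mean, cal$variable)
  sds <- stats::setNames(cal$sd, cal$variable)
  if (!is.null(env_means)) means[names(env_means)] <- env_means
  if (!is.null(env_sds)) sds[names(env_sds)] <- env_sds

  cfg <- structure(list(
    start_date = as.Date(start_date),
    n_days = as.integer(n_days),
    baseline_level = baseline_level,
    yearly_trend = yearly_trend,
    annual_amplitude = annual_amplitude,
    weekly_effects = weekly_effects,
    holiday_effect = holiday_effect,
    env_effect_coeffs = env_effect_coeffs,
    dispersion = dispersion,
    env_means = means,
    env_sds = sds,
    env_noise = isTRUE(env_noise),
    missing_rate = missing_rate,
    holidays = holidays,
    seed = as.integer(seed)
  ), class = "ha_generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$start_date)) stop_cfg("start_date", "is not a valid date")
  L <- max(c(1L, lengths(cfg$env_effect_coeffs)))
  if (is.na(cfg$n_days) || cfg$n_days < 2L * L + 10L)
    stop_cfg("n_days", sprintf("must be at least 2*L + 10 = %d", 2L * L + 10L))
  if (!is.numeric(cfg$baseline_level) || cfg$baseline_level <= 0)
    stop_cfg("baseline_level", "must be a positive real")
  if (length(cfg$weekly_effects) != 7L)
    stop_cfg("weekly_effects", "must have length 7 (Monday first)")
  if (any(cfg$env_sds <= 0)) stop_cfg("env_sds", "must all be positive")
  bad <- setdiff(names(cfg$env_effect_coeffs), names(cfg$env_means))
  if (length(bad))
    stop_cfg("env_effect_coeffs", paste("names unknown variable(s):",
                                        paste(bad, collapse = ", ")))
  if (is.character(cfg$dispersion)) {
    if (!cfg$dispersion %in% c("poisson", "none"))
      stop_cfg("dispersion", "string form must be 'poisson' or 'none'")
  } else if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0) {
    stop_cfg("dispersion", "must be positive, 'poisson' or 'none'")
  }
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 ||
      cfg$missing_rate >= 1)
    stop_cfg("missing_rate", "must lie in [0, 1)")
  invisible(cfg)
}

# one standardized (mean 0, var ~1) series: seasonal cosine plus AR(1) noise,
# innovation variance chosen so the stationary total variance is 1
seasonal_ar1 <- function(doy, amp, peak, phi = 0.7, noise = TRUE,
                         innovations = NULL) {
  n <- length(doy)
  seasonal <- amp * cos(2 * pi * (doy - peak) / 365.25)
  if (!noise) return(seasonal)
  resid_var <- max(1 - amp^2 / 2, 0.05)
  innov_sd <- sqrt(resid_var * (1 - phi^2))
  eps <- if (is.null(innovations)) stats::rnorm(n) else innovations
  e <- stats::filter(innov_sd * eps, phi, method = "recursive",
                     init = stats::rnorm(1, 0, sqrt(resid_var)))
  seasonal + as.numeric(e)
}

#' Generate a synthetic daily admissions panel
#'
#' Simulates a study-shaped daily panel: a non-negative integer admission
#' count per day, driven by a log-linear intensity (rising yearly trend,
#' annual and weekly seasonality, holiday dips, short-term lagged effects of
#' the environmental series), plus ten environmental columns generated as
#' seasonal sinusoids with lag-1 autocorrelated noise and calibrated means
#' and SDs.  \code{pmc = pm10 - pm25} holds exactly by construction, and
#' \code{aqi} is a deterministic monotone summary of the pollutant columns.
#'
#' @param config A [generator_config()].
#' @return A \code{data.frame} of class \code{ha_panel} with columns
#'   \code{date}, \code{ha_count} and the ten [env_variables()].  The true
#'   log-intensity is attached as attribute \code{"log_intensity"} so tests
#'   can de-trend against the known ground truth.
#' @export
generate_panel <- function(config) {
  validate_generator_config(config)
  cfg <- config
  set.seed(derive_seed(cfg$seed, 101L))
  dates <- seq(cfg$start_date, by = "day", length.out = cfg$n_days)
  doy <- as.integer(strftime(dates, "%j"))
  cal <- env_calibration()

  # environmental series on the standardized scale; pm10 = pm25 + pmc with
  # correlated innovations so the implied pm10 SD matches its calibration
  z <- matrix(0, nrow = cfg$n_days, ncol = nrow(cal),
              dimnames = list(NULL, cal$variable))
  innov <- matrix(stats::rnorm(cfg$n_days * nrow(cal)), ncol = nrow(cal),
                  dimnames = list(NULL, cal$variable))
  innov[, "pmc"] <- 0.8 * innov[, "pm25"] + 0.6 * innov[, "pmc"]
  for (v in setdiff(cal$variable, c("pm10", "aqi"))) {
    i <- match(v, cal$variable)
    z[, v] <- seasonal_ar1(doy, cal$season_amp[i], cal$season_peak[i],
                           noise = cfg$env_noise, innovations = innov[, v])
  }
  env <- sweep(sweep(z, 2, cfg$env_sds[colnames(z)], `*`), 2,
               cfg$env_means[colnames(z)], `+`)
  for (v in setdiff(colnames(env), c("tem", "pm10", "aqi")))
    env[, v] <- pmax(env[, v], 0.02 * cfg$env_means[v])
  env[, "pm10"] <- env[, "pm25"] + env[, "pmc"]  # identity pmc = pm10 - pm25
  ref <- aqi_reference()
  env[, "aqi"] <- 100 * do.call(pmax, lapply(names(ref),
                                             function(v) env[, v] / ref[v]))

  # log intensity of the count process
  years_elapsed <- as.numeric(dates - dates[1]) / 365.25
  dow <- dow_monday1(dates)
  holidays <- cfg$holidays %||%
    default_holidays(unique(as.integer(strftime(dates, "%Y"))))
  hol <- dates %in% holidays
  log_int <- log(cfg$baseline_level) +
    cfg$yearly_trend * years_elapsed +
    cfg$annual_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    cfg$weekly_effects[dow] +
    cfg$holiday_effect * hol
  zstd <- sweep(sweep(env, 2, cfg$env_means[colnames(env)], `-`), 2,
                cfg$env_sds[colnames(env)], `/`)
  for (v in names(cfg$env_effect_coeffs)) {
    coefs <- cfg$env_effect_coeffs[[v]]
    for (x in seq_along(coefs)) {
      if (coefs[x] == 0) next
      lagged <- c(rep(0, x), zstd[seq_len(cfg$n_days - x), v])
      log_int <- log_int + coefs[x] * lagged
    }
  }

  mu <- exp(log_int)
  counts <- if (identical(cfg$dispersion, "none")) {
    as.integer(round(mu))
  } else if (identical(cfg$dispersion, "poisson")) {
    stats::rpois(cfg$n_days, mu)
  } else {
    stats::rnbinom(cfg$n_days, size = cfg$dispersion, mu = mu)
  }

  panel <- data.frame(date = dates, ha_count = as.integer(counts))
  panel[cal$variable] <- as.data.frame(env)[cal$variable]
  class(panel) <- c("ha_panel", "data.frame")
  attr(panel, "log_intensity") <- log_int
  if (cfg$missing_rate > 0)
    panel <- inject_missing(panel, cfg$missing_rate,
                            derive_seed(cfg$seed, 202L))
  panel
}

#' @export
print.ha_panel <- function(x, ...) {
  cat(sprintf("<ha_panel> %d days (%s to %s), mean daily count %.1f\n",
              nrow(x), min(x$date), max(x$date), mean(x$ha_count)))
  n_miss <- sum(!stats::complete.cases(x[env_variables()]))
  if (n_miss > 0) cat(sprintf("  %d day(s) with missing environmental cells\n",
                              n_miss))
  invisible(x)
}

#' Blank environmental cells on randomly chosen days
#'
#' Sets all ten environmental columns to \code{NA} on exactly
#' \code{round(rate * n_days)} days, chosen uniformly without replacement.
#' The day-level joint blanking matches how station outages hit every
#' variable at once; \code{ha_count} and \code{date} are never touched.
#'
#' @param panel An \code{ha_panel}.
#' @param rate Fraction of days in \code{[0, 1)}.
#' @param seed Integer seed for the day choice.
#' @return The panel with missing cells.
#' @export
inject_missing <- function(panel, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("missing rate must lie in [0, 1)", call. = FALSE)
  n_blank <- round(rate * nrow(panel))
  if (n_blank == 0) return(panel)
  set.seed(derive_seed(seed, 7L))
  days <- sample.int(nrow(panel), n_blank)
  panel[days, env_variables()] <- NA_real_
  panel
}

#' Descriptive statistics of a daily panel
#'
#' Per-column mean, sample SD, minimum, quartiles and maximum for the count
#' and every environmental column, computed over non-missing cells
#' (percentiles use R's default quantile rule, type 7).
#'
#' @param panel A non-empty \code{ha_panel} (or any data.frame whose
#'   non-date columns are numeric).
#' @return A \code{data.frame} with one row per column.
#' @export
panel_summary <- function(panel) {
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  cols <- setdiff(names(panel), "date")
  rows <- lapply(cols, function(v) {
    x <- panel[[v]][!is.na(panel[[v]])]
    q <- stats::quantile(x, c(.25, .5, .75), names = FALSE)
    data.frame(variable = v, mean = mean(x), sd = sample_sd(x),
               min = min(x), q25 = q[1], median = q[2], q75 = q[3],
               max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
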