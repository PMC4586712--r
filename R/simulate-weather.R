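#' Summer calendar helper
#'
#' Builds the June--August calendar used throughout: `days_per_summer`
#' consecutive days starting June 1 of each year.
#'
#' @param n_years number of summers.
#' @param days_per_summer days per summer.
#' @param start_year first calendar year.
#' @return a `Date` vector of length `n_years * days_per_summer`.
#' @export
summer_dates <- function(n_years, days_per_summer = 92L, start_year = 1990L) {
  stopifnot(n_years >= 1L, days_per_summer >= 1L)
  years <- start_year + seq_len(n_years) - 1L
  do.call(c, lapply(years, function(y) {
    as.Date(sprintf("%d-06-01", y)) + seq_len(days_per_summer) - 1L
  }))
}

# deterministic within-summer seasonal cycle for a date: a sinusoid peaking on
# July 15, centred so that its mean over the canonical summer window is zero
# (hence the series mean equals temp_mean_c in expectation)
seasonal_component <- function(dates, amplitude, days_per_summer = 92L) {
  doy <- as.POSIXlt(dates)$yday + 1L
  raw <- function(d) amplitude * cos(2 * pi * (d - 196) / 365)
  window <- 152L + seq_len(days_per_summer) - 1L  # Jun 1 = doy 152, non-leap
  raw(doy) - mean(raw(window))
}

#' Generate a synthetic daily summer weather series
#'
#' Daily mean temperature is a deterministic within-summer sinusoid (peak
#' mid-July) plus stationary AR(1) Gaussian noise; the noise variance is set so
#' that the marginal SD of the full series (seasonal cycle included) equals
#' `temp_sd_c`. Relative humidity is i.i.d. Gaussian truncated to [0, 100].
#' The AR(1) chain runs across summer boundaries.
#'
#' @param config a [simulation_config()].
#' @param n_days number of days to generate (default: the config's full
#'   `n_years * days_per_summer` calendar).
#' @param seed RNG seed for this series (default: derived from the config's
#'   master seed by the weather stream offset).
#' @param start_year first calendar year of the series.
#' @return a data frame with columns `date`, `temp_c`, `humidity_pct`.
#' @export
generate_temperature_series <- function(config,
                                        n_days = config$n_years * config$days_per_summer,
                                        seed = derive_seed(config$seed, "weather"),
                                        start_year = 1990L) {
  validate_simulation_config(config)
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  n_summers <- ceiling(n_days / config$days_per_summer)
  dates <- summer_dates(n_summers, config$days_per_summer, start_year)[seq_len(n_days)]

  seas <- seasonal_component(dates, config$seasonal_amplitude_c,
                             config$days_per_summer)
  # noise marginal SD chosen so total SD (seasonal + noise) hits temp_sd_c
  sd_noise <- sqrt(max(config$temp_sd_c^2 - stats::var(seas), 0))

  set.seed(seed)
  phi <- config$temp_ar1
  z <- numeric(n_days)
  if (sd_noise > 0) {
    innov_sd <- sd_noise * sqrt(1 - phi^2)
    z[1] <- stats::rnorm(1, 0, sd_noise)
    if (n_days > 1) {
      eps <- stats::rnorm(n_days - 1, 0, innov_sd)
      for (i in 2:n_days) z[i] <- phi * z[i - 1] + eps[i - 1]
    }
  }
  hum <- stats::rnorm(n_days, config$humidity_mean_pct, config$humidity_sd_pct)
  hum <- pmin(pmax(hum, 0), 100)

  data.frame(date = dates,
             temp_c = config$temp_mean_c + seas + z,
             humidity_pct = hum)
}

#' Generate a synthetic sex/age life table
#'
#' Remaining life expectancy by sex and single year of age from a Gompertz
#' mortality schedule: hazard h(x) = a exp(bx), with the male level `a` solved
#' so that male life expectancy at birth equals `male_e0`, and the female level
#' solved so that the female-minus-male gap at birth equals `sex_gap_years`.
#' Expectancies are computed by adaptive quadrature of the conditional survival
#' curve.
#'
#' @param max_age oldest age (completed years) in the table.
#' @param sex_gap_years female minus male life expectancy at birth, years.
#' @param male_e0 male life expectancy at birth, years.
#' @param gompertz_b Gompertz log-hazard slope per year of age.
#' @return a `life_table` data frame with columns `sex` ("female"/"male"),
#'   `age` (0..max_age) and `ex` (remaining life expectancy, years).
#' @export
generate_life_table <- function(max_age = 100L, sex_gap_years = 4,
                                male_e0 = 77, gompertz_b = 0.09) {
  if (max_age < 1L) stop("max_age must be >= 1", call. = FALSE)
  b <- gompertz_b

  e_at <- function(a, x) {
    stats::integrate(function(t) exp(-(a / b) * (exp(b * (x + t)) - exp(b * x))),
                     0, Inf, rel.tol = 1e-10)$value
  }
  solve_a <- function(target_e0) {
    stats::uniroot(function(a) e_at(a, 0) - target_e0,
                   interval = c(1e-8, 0.05), tol = 1e-12)$root
  }

  a_m <- solve_a(male_e0)
  a_f <- solve_a(male_e0 + sex_gap_years)
  ages <- 0:max_age
  tab <- rbind(
    data.frame(sex = "female", age = ages,
               ex = vapply(ages, function(x) e_at(a_f, x), numeric(1))),
    data.frame(sex = "male", age = ages,
               ex = vapply(ages, function(x) e_at(a_m, x), numeric(1)))
  )
  structure(tab,
            class = c("life_table", "data.frame"),
            max_age = as.integer(max_age),
            gompertz = c(a_female = a_f, a_male = a_m, b = b))
}
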