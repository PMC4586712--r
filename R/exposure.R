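#' Exposure-response model configuration
#'
#' Choices for the DYLLD-temperature model: a hockey-stick heat term at lag 0,
#' selected by profile deviance over a grid of candidate thresholds, inside a
#' GLM adjusted for season (natural cubic spline of day-of-summer), a yearly
#' trend and same-day humidity.
#'
#' @param season_spline_df degrees of freedom of the day-of-summer spline.
#' @param year_trend "linear" (numeric year), "factor" (one level per year)
#'   or "none".
#' @param humidity_term "linear" or "none".
#' @param threshold_grid_step grid step (degC) for candidate thresholds.
#' @param threshold_grid_quantiles temperature quantiles bounding the grid.
#' @param family "quasi-poisson-log" (multiplicative model on nonnegative
#'   DYLLD) or "gaussian-identity" (additive sensitivity model).
#' @param floor_negative_dylld floor negative disparity days at 0 before a
#'   log-link fit (the floored fraction is recorded on the fit).
#' @return a `model_config` list.
#' @export
model_config <- function(season_spline_df = 3L,
                         year_trend = c("linear", "factor", "none"),
                         humidity_term = c("linear", "none"),
                         threshold_grid_step = 1,
                         threshold_grid_quantiles = c(0.50, 0.98),
                         family = c("quasi-poisson-log", "gaussian-identity"),
                         floor_negative_dylld = TRUE) {
  cfg <- list(season_spline_df = as.integer(season_spline_df),
              year_trend = match.arg(year_trend),
              humidity_term = match.arg(humidity_term),
              threshold_grid_step = threshold_grid_step,
              threshold_grid_quantiles = threshold_grid_quantiles,
              family = match.arg(family),
              floor_negative_dylld = floor_negative_dylld)
  class(cfg) <- "model_config"
  cfg
}

build_model_frame <- function(dylld, weather, config) {
  d <- merge(dylld, weather, by = "date")
  if (nrow(d) < nrow(dylld))
    stop("weather series does not cover every DYLLD day", call. = FALSE)
  d <- d[order(d$date), , drop = FALSE]
  lt <- as.POSIXlt(d$date)
  d$year <- lt$year + 1900L
  # day-of-summer: days since June 1 of the same year
  d$dos <- as.integer(d$date - as.Date(sprintf("%d-06-01", d$year))) + 1L
  d$y <- d$dylld
  floored <- 0
  if (config$family == "quasi-poisson-log") {
    floored <- mean(d$y < 0)
    if (config$floor_negative_dylld) d$y <- pmax(d$y, 0)
    else if (any(d$y < 0))
      stop("log-link family needs nonnegative DYLLD; enable floor_negative_dylld",
           call. = FALSE)
  }
  attr(d, "fraction_floored") <- floored
  d
}

fit_one_threshold <- function(d, tau, config) {
  d$heat <- pmax(d$temp_c - tau, 0)
  rhs <- "heat"
  if (config$season_spline_df > 0)
    rhs <- c(rhs, sprintf("splines::ns(dos, df = %d)", config$season_spline_df))
  if (config$year_trend != "none" && length(unique(d$year)) > 1L)
    rhs <- c(rhs, if (config$year_trend == "factor") "factor(year)" else "year")
  if (config$humidity_term == "linear") rhs <- c(rhs, "humidity_pct")
  fam <- if (config$family == "quasi-poisson-log") stats::quasipoisson("log")
         else stats::gaussian()
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  stats::glm(form, family = fam, data = d,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100L))
}

#' Fit the DYLLD-temperature threshold model
#'
#' For each candidate threshold tau on a grid between the configured
#' temperature quantiles, fits a GLM of the daily disparity on the lag-0 heat
#' excess `(T_d - tau)+` with season-spline, year-trend and humidity
#' adjustments, and keeps the tau minimizing the residual deviance (the
#' profile-deviance breakpoint estimate). Under the default quasi-Poisson
#' log-link family the heat coefficient is the log relative risk per degC
#' above threshold.
#'
#' @param dylld a [dylld_series()] data frame.
#' @param weather daily weather covering all DYLLD days (`date`, `temp_c`,
#'   `humidity_pct`).
#' @param config a [model_config()].
#' @return an `exposure_response_fit` with elements `threshold_c`,
#'   `log_rr_per_deg`, `slope_se`, `coef`, `coef_covariance`,
#'   `period_mean_dylld`, `deviance_profile`, `n_days_used`,
#'   `fraction_floored`, `warnings`, `family`, and the model `data`.
#' @export
fit_exposure_response <- function(dylld, weather, config = model_config()) {
  d <- build_model_frame(dylld, weather, config)
  if (length(unique(d$year)) < 2L)
    stop("need at least 2 summers of data", call. = FALSE)

  qs <- stats::quantile(d$temp_c, config$threshold_grid_quantiles, names = FALSE)
  # candidates aligned to multiples of the grid step (thresholds are reported
  # on that scale), restricted to the quantile window
  step <- config$threshold_grid_step
  lo <- ceiling(qs[1] / step) * step
  hi <- floor(qs[2] / step) * step
  grid <- if (qs[1] == qs[2]) qs[1]
          else if (lo > hi) mean(qs)
          else seq(lo, hi, by = step)

  fits <- vector("list", length(grid))
  dev <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    f <- tryCatch(fit_one_threshold(d, grid[i], config), error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      fits[[i]] <- f
      dev[i] <- f$deviance
    }
  }
  if (all(is.na(dev)))
    stop("model did not converge at any candidate threshold (grid ",
         paste(round(range(grid), 2), collapse = " to "), ")", call. = FALSE)

  best <- which.min(dev)
  f <- fits[[best]]
  warnings <- character()
  n_above <- sum(d$temp_c > grid[best])
  if (n_above < 10L)
    warnings <- c(warnings, sprintf(
      "only %d days above the selected threshold %.1f degC", n_above, grid[best]))

  slope <- unname(stats::coef(f)["heat"])
  se <- sqrt(stats::vcov(f)["heat", "heat"])
  # the threshold is itself selected from the deviance profile, so a plain
  # 1.96 interval on the slope is anti-conservative; calibrate the critical
  # value against the joint null distribution of the candidate slope
  # statistics (single-step max-|z| adjustment over the profiled grid)
  zc <- selection_critical_value(fits, f)
  structure(list(
    threshold_c = grid[best],
    log_rr_per_deg = slope,
    slope_se = se,
    slope_ci = c(slope - zc * se, slope + zc * se),
    slope_crit = zc,
    coef = stats::coef(f),
    coef_covariance = stats::vcov(f),
    period_mean_dylld = mean(d$y),
    deviance_profile = data.frame(threshold_c = grid, deviance = dev),
    n_days_used = nrow(d),
    n_days_above = n_above,
    fraction_floored = attr(d, "fraction_floored"),
    warnings = warnings,
    family = config$family,
    config = config,
    data = d[, c("date", "year", "temp_c", "humidity_pct", "dylld", "y")],
    glm = f
  ), class = "exposure_response_fit")
}

# 95% critical value for the selected heat slope, accounting for the search
# over candidate thresholds. The candidate slope estimates are (asymptotically)
# jointly normal linear functionals of the daily series; their correlation
# matrix follows from the candidate design matrices and working weights, and
# the critical value is the 0.95 quantile of max |Z| over that correlated
# Gaussian vector (single-step adjustment), computed by fixed-seed Monte Carlo
# without disturbing the caller's RNG stream.
selection_critical_value <- function(fits, selected, n_mc = 20000L) {
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  k <- length(fits)
  if (k <= 1L) return(stats::qnorm(0.975))

  mu0 <- stats::fitted(selected)  # variance proxy under the fitted model
  infl <- lapply(fits, function(f) {
    X <- stats::model.matrix(f)
    w <- f$weights
    e <- as.numeric(colnames(X) == "heat")
    b <- solve(crossprod(X, w * X), e)
    w * as.numeric(X %*% b)       # slope_i ~ sum_d a_id * y_d
  })
  C <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    C[i, j] <- sum(infl[[i]] * mu0 * infl[[j]])
    C[j, i] <- C[i, j]
  }
  R <- stats::cov2cor(C)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(104729L)
  Z <- MASS::mvrnorm(n_mc, mu = rep(0, k), Sigma = R)
  unname(stats::quantile(apply(abs(Z), 1, max), 0.95))
}

#' @export
print.exposure_response_fit <- function(x, ...) {
  cat("DYLLD-temperature threshold model (", x$family, ")\n", sep = "")
  cat(sprintf("  threshold: %.1f degC (%d days above, of %d used)\n",
              x$threshold_c, x$n_days_above, x$n_days_used))
  cat(sprintf("  slope above threshold: %.4f per degC (SE %.4f)\n",
              x$log_rr_per_deg, x$slope_se))
  if (x$fraction_floored > 0)
    cat(sprintf("  %.1f%% of days had negative DYLLD floored at 0\n",
                100 * x$fraction_floored))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Relative-risk curve from a fitted threshold model
#'
#' RR(t) = 1 at and below the threshold; above it, under the log-link family,
#' `exp(slope * (t - threshold))`. Under the Gaussian identity family RR is
#' the fitted excess relative to the period mean disparity:
#' `1 + slope * (t - threshold) / period_mean_dylld`.
#'
#' @param fit an `exposure_response_fit`.
#' @param temperatures numeric grid of temperatures (degC).
#' @param slope optional slope override (used internally for uncertainty
#'   draws).
#' @return numeric vector of RRs.
#' @export
rr_curve <- function(fit, temperatures, slope = fit$log_rr_per_deg) {
  x <- pmax(temperatures - fit$threshold_c, 0)
  if (fit$family == "quasi-poisson-log") exp(slope * x)
  else 1 + slope * x / fit$period_mean_dylld
}

#' Summer DYLLD attributable to above-threshold temperatures
#'
#' In "observed-dylld" mode (historical estimates) the attributable burden is
#' the attributable-fraction form summed over observed hot days:
#' `sum_d DYLLD_d * (RR(T_d) - 1) / RR(T_d)`. In "constant-baseline" mode
#' (projections, where no future disparity series exists) it is the excess
#' form on the period-mean disparity: `sum_d mean_DYLLD * (RR(T_d) - 1)`.
#' Either sum is divided by the number of summers covered and expressed per
#' 100,000 persons. Uncertainty comes from seeded multivariate-normal draws of
#' the model coefficients propagated through the same sum.
#'
#' @param fit an `exposure_response_fit`.
#' @param weather daily series with `date` and `temp_c`; defaults to the
#'   fitting data (the usual choice for observed-dylld mode).
#' @param population population at risk (persons).
#' @param mode "observed-dylld" or "constant-baseline".
#' @param n_draws number of coefficient draws for the standard error.
#' @param seed RNG seed for the draws.
#' @return a list with `rate` (years per 100,000 per summer), `se`, `ci`
#'   (percentile 95%), `n_summers`, `n_days_above`, and the draw vector
#'   `draws`.
#' @export
attributable_rate <- function(fit, weather = NULL, population,
                              mode = c("observed-dylld", "constant-baseline"),
                              n_draws = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(population > 0)
  if (is.null(weather)) weather <- fit$data
  n_summers <- length(unique(as.POSIXlt(weather$date)$year))

  hot <- weather$temp_c > fit$threshold_c
  if (!any(hot)) {
    warning("no days above the threshold; attributable rate is 0")
    return(list(rate = 0, se = 0, ci = c(0, 0), n_summers = n_summers,
                n_days_above = 0L, draws = rep(0, n_draws)))
  }
  temps <- weather$temp_c[hot]

  burden_for_slope <- function(slope) {
    rr <- rr_curve(fit, temps, slope = slope)
    if (mode == "observed-dylld") {
      obs <- if (!is.null(weather$y)) weather$y else {
        m <- match(weather$date, fit$data$date)
        if (anyNA(m[hot]))
          stop("observed-dylld mode needs the fitted disparity series for every hot day",
               call. = FALSE)
        fit$data$y[m]
      }
      sum(obs[hot] * (rr - 1) / rr)
    } else {
      sum(fit$period_mean_dylld * (rr - 1))
    }
  }

  to_rate <- function(burden) burden / n_summers / population * 1e5
  rate <- to_rate(burden_for_slope(fit$log_rr_per_deg))

  set.seed(seed)
  ks <- draw_slopes(fit, n_draws)
  draws <- to_rate(vapply(ks, burden_for_slope, numeric(1)))
  list(rate = rate,
       se = stats::sd(draws),
       ci = unname(stats::quantile(draws, c(0.025, 0.975))),
       n_summers = n_summers,
       n_days_above = sum(hot),
       draws = draws)
}

# multivariate-normal draws of the full coefficient vector; returns the heat
# slopes (the only coefficient the RR curve depends on)
draw_slopes <- function(fit, n_draws) {
  sims <- MASS::mvrnorm(n_draws, mu = fit$coef, Sigma = fit$coef_covariance)
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = n_draws)
  colnames(sims) <- names(fit$coef)
  sims[, "heat"]
}
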