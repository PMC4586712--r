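#' Empirical quantile-quantile bias correction
#'
#' Builds the empirical quantile transfer from a scenario's historical series
#' to the observed series and applies it to a target series. When the two
#' calibration series have equal length the transfer interpolates linearly
#' between matched order statistics; otherwise between type-7 quantiles at
#' plotting positions of the shorter series (at most 2000 knots). Target
#' values beyond the calibration range are shifted by the offset between the
#' endpoint order statistics, so the mapping stays monotone everywhere.
#'
#' @param observed numeric observed daily temperatures (degC).
#' @param scenario_hist numeric scenario temperatures over the same climate
#'   period as `observed`.
#' @param target numeric series to correct (historical or future scenario
#'   days).
#' @return corrected numeric series, same length and order as `target`.
#' @export
quantile_map <- function(observed, scenario_hist, target) {
  if (length(observed) < 30L || length(scenario_hist) < 30L)
    stop("need >= 30 values in both calibration series for quantile mapping",
         call. = FALSE)
  if (!length(target)) stop("target series is empty", call. = FALSE)

  if (length(observed) == length(scenario_hist)) {
    kx <- sort(scenario_hist)
    ky <- sort(observed)
  } else {
    m <- min(length(observed), length(scenario_hist), 2000L)
    p <- stats::ppoints(m)
    kx <- stats::quantile(scenario_hist, p, names = FALSE, type = 7)
    ky <- stats::quantile(observed, p, names = FALSE, type = 7)
  }
  # collapse tied knots (mean of mapped values) so interpolation is well posed
  if (anyDuplicated(kx)) {
    ky <- as.numeric(tapply(ky, kx, mean))
    kx <- sort(unique(kx))
  }
  out <- stats::approx(kx, ky, xout = target, rule = 1)$y
  lo <- target < kx[1]
  hi <- target > kx[length(kx)]
  out[lo] <- target[lo] + (ky[1] - kx[1])
  out[hi] <- target[hi] + (ky[length(ky)] - kx[length(kx)])
  out
}

#' Per-scenario climate-change impacts on attributable DYLLD
#'
#' For every scenario: bias-corrects the historical and future temperature
#' series against observations by [quantile_map()] (calibrated on the
#' historical period), computes constant-baseline attributable DYLLD rates for
#' the summer days of each period with the fitted exposure-response model held
#' fixed (no acclimatization, constant population), and forms the impact of
#' climate change (ICC) as the future/historical rate ratio. The log-ICC
#' standard error comes from seeded coefficient draws shared between numerator
#' and denominator, so their correlation is honoured.
#'
#' @param fit an `exposure_response_fit`.
#' @param ensemble a `scenario_ensemble` (or list of scenario pairs).
#' @param observed observed daily weather (`date`, `temp_c`) used as the
#'   quantile-mapping reference.
#' @param population population at risk.
#' @param seed RNG seed; scenario s uses `seed + s` for its shared draws.
#' @param n_draws coefficient draws per scenario.
#' @return a data frame of class `scenario_impacts`: `scenario_id`,
#'   `historical_rate`, `future_rate` (years per 100,000 per summer), `icc`,
#'   `log_icc_se`, `warming_delta_c`, `excluded`.
#' @export
scenario_impacts <- function(fit, ensemble, observed, population,
                             seed = 1L, n_draws = 1000L) {
  if (!length(ensemble)) stop("ensemble is empty", call. = FALSE)
  obs_t <- observed$temp_c

  one <- function(s, i) {
    hist_c <- quantile_map(obs_t, s$historical$temp_c, s$historical$temp_c)
    fut_c <- quantile_map(obs_t, s$historical$temp_c, s$future$temp_c)
    hist_w <- data.frame(date = s$historical$date, temp_c = hist_c)
    fut_w <- data.frame(date = s$future$date, temp_c = fut_c)

    set.seed(as.integer((seed + i) %% .Machine$integer.max))
    slopes <- draw_slopes(fit, n_draws)

    rate_of <- function(w, slope = fit$log_rr_per_deg) {
      hot <- w$temp_c > fit$threshold_c
      n_sum <- length(unique(as.POSIXlt(w$date)$year))
      if (!any(hot)) return(0)
      rr <- rr_curve(fit, w$temp_c[hot], slope = slope)
      sum(fit$period_mean_dylld * (rr - 1)) / n_sum / population * 1e5
    }
    h <- rate_of(hist_w)
    f <- rate_of(fut_w)
    icc <- if (h > 0) f / h else NA_real_

    log_se <- NA_real_
    log_f_se <- NA_real_
    if (h > 0) {
      hd <- vapply(slopes, function(b) rate_of(hist_w, b), numeric(1))
      fd <- vapply(slopes, function(b) rate_of(fut_w, b), numeric(1))
      ok <- hd > 0 & fd > 0
      log_se <- stats::sd(log(fd[ok] / hd[ok]))
      log_f_se <- stats::sd(log(fd[fd > 0]))
    }
    data.frame(scenario_id = s$scenario_id,
               historical_rate = h, future_rate = f,
               icc = icc, log_icc_se = log_se,
               log_future_rate_se = log_f_se,
               warming_delta_c = mean(fut_c) - mean(hist_c),
               excluded = !(h > 0))
  }

  out <- do.call(rbind, Map(one, ensemble, seq_along(ensemble)))
  rownames(out) <- NULL
  if (any(out$excluded))
    warning(sum(out$excluded),
            " scenario(s) had a zero historical attributable rate and are flagged",
            " for exclusion from pooling")
  class(out) <- c("scenario_impacts", "data.frame")
  out
}

#' Per-scenario mean temperature shift
#'
#' The averaged difference between each scenario's future and historical daily
#' mean temperatures (raw series, no bias correction), with a standard error
#' from daily sampling variability.
#'
#' @param ensemble a `scenario_ensemble`.
#' @return a data frame `scenario_id`, `delta_c`, `se`.
#' @export
temperature_shift <- function(ensemble) {
  if (!length(ensemble)) stop("ensemble is empty", call. = FALSE)
  out <- do.call(rbind, lapply(ensemble, function(s) {
    f <- s$future$temp_c
    h <- s$historical$temp_c
    data.frame(scenario_id = s$scenario_id,
               delta_c = mean(f) - mean(h),
               se = sqrt(stats::var(f) / length(f) + stats::var(h) / length(h)))
  }))
  rownames(out) <- NULL
  out
}
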