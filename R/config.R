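#' Simulation configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data-generating process: the scale of
#' the mortality series, the designed per-tercile heat effects, the weather
#' model, and the climate-scenario ensemble. Defaults emulate a large northern
#' city over 18 summers: ~37 non-accidental deaths per summer day, summer daily
#' mean temperature around 20.4 degC (overall SD 3.24 degC) with day-to-day
#' autocorrelation, a heat threshold at 23 degC, heat effects strongest in the
#' most deprived tercile, and a 30-member scenario ensemble warming by about
#' 1.35 degC on average between its historical and future periods.
#'
#' @param n_years number of summer seasons in the observed series.
#' @param days_per_summer days per summer season (92 for June--August).
#' @param baseline_deaths_per_day Poisson mean of total daily deaths at or
#'   below the heat threshold.
#' @param ses_tercile_probs length-3 probabilities (low-, mid-, high-SES share
#'   of deaths); must sum to 1.
#' @param group_heat_log_rr length-3 log relative risk per degC above
#'   threshold, ordered (low, mid, high SES); the low-SES value must be the
#'   largest (the designed vulnerability gradient).
#' @param true_threshold_c designed heat threshold in degC.
#' @param temp_mean_c,temp_sd_c summer mean and overall SD of daily mean
#'   temperature (degC). The SD is the marginal SD of the series including the
#'   seasonal cycle.
#' @param temp_ar1 lag-1 autocorrelation of the temperature noise, in [0, 1).
#' @param seasonal_amplitude_c amplitude (degC) of the within-summer sinusoid
#'   peaking in mid-July.
#' @param humidity_mean_pct,humidity_sd_pct daily relative humidity moments
#'   (%); values are truncated to [0, 100].
#' @param n_scenarios number of climate scenarios in the ensemble.
#' @param scenario_years summers per scenario period (30 for 1981--2010 vs
#'   2021--2050 style periods).
#' @param scenario_bias_sd_c SD (degC) of the scenario-specific mean bias
#'   relative to observations (what quantile mapping must remove).
#' @param scenario_warming_mean_c,scenario_warming_sd_c mean and SD (degC) of
#'   the per-scenario warming delta between the future and historical periods.
#' @param max_age oldest age (completed years) in the life table.
#' @param age_mean,age_sd moments of the truncated-Gaussian age-at-death
#'   distribution (truncated to [35, max_age]).
#' @param seed master seed; per-output-type streams are derived from it by
#'   fixed offsets so e.g. adding scenarios never perturbs the death series.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_years = 18L,
                              days_per_summer = 92L,
                              baseline_deaths_per_day = 37,
                              ses_tercile_probs = c(1, 1, 1) / 3,
                              group_heat_log_rr = c(low = 0.06, mid = 0.03, high = 0.01),
                              true_threshold_c = 23,
                              temp_mean_c = 20.4,
                              temp_sd_c = 3.24,
                              temp_ar1 = 0.55,
                              seasonal_amplitude_c = 1.5,
                              humidity_mean_pct = 70,
                              humidity_sd_pct = 10,
                              n_scenarios = 30L,
                              scenario_years = 30L,
                              scenario_bias_sd_c = 1,
                              scenario_warming_mean_c = 1.35,
                              scenario_warming_sd_c = 0.25,
                              max_age = 100L,
                              age_mean = 78,
                              age_sd = 12,
                              seed = 1L) {
  cfg <- list(
    n_years = as.integer(n_years),
    days_per_summer = as.integer(days_per_summer),
    baseline_deaths_per_day = baseline_deaths_per_day,
    ses_tercile_probs = ses_tercile_probs,
    group_heat_log_rr = group_heat_log_rr,
    true_threshold_c = true_threshold_c,
    temp_mean_c = temp_mean_c,
    temp_sd_c = temp_sd_c,
    temp_ar1 = temp_ar1,
    seasonal_amplitude_c = seasonal_amplitude_c,
    humidity_mean_pct = humidity_mean_pct,
    humidity_sd_pct = humidity_sd_pct,
    n_scenarios = as.integer(n_scenarios),
    scenario_years = as.integer(scenario_years),
    scenario_bias_sd_c = scenario_bias_sd_c,
    scenario_warming_mean_c = scenario_warming_mean_c,
    scenario_warming_sd_c = scenario_warming_sd_c,
    max_age = as.integer(max_age),
    age_mean = age_mean,
    age_sd = age_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_years < 1L || cfg$days_per_summer < 1L)
    stop("n_years and days_per_summer must be positive", call. = FALSE)
  if (cfg$baseline_deaths_per_day < 0)
    stop("baseline_deaths_per_day must be nonnegative", call. = FALSE)
  p <- cfg$ses_tercile_probs
  if (length(p) != 3L || any(p <= 0))
    stop("ses_tercile_probs must be 3 strictly positive probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop("ses_tercile_probs must sum to 1 (within 1e-12)", call. = FALSE)
  b <- cfg$group_heat_log_rr
  if (length(b) != 3L)
    stop("group_heat_log_rr must have 3 elements (low, mid, high SES)", call. = FALSE)
  if (b[[1]] < max(b))
    stop("group_heat_log_rr: the low-SES tercile must carry the largest heat effect",
         call. = FALSE)
  if (cfg$temp_ar1 < 0 || cfg$temp_ar1 >= 1)
    stop("temp_ar1 must lie in [0, 1)", call. = FALSE)
  if (cfg$temp_sd_c < 0 || cfg$humidity_sd_pct < 0)
    stop("standard deviations must be nonnegative", call. = FALSE)
  if (cfg$n_scenarios < 1L) stop("n_scenarios must be >= 1", call. = FALSE)
  if (cfg$max_age < 36L) stop("max_age must exceed the age floor of 35", call. = FALSE)
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d summers x %d days, %.1f deaths/day baseline\n",
              x$n_years, x$days_per_summer, x$baseline_deaths_per_day))
  cat(sprintf("  heat threshold %.1f degC; log-RR/degC (low,mid,high SES) = %s\n",
              x$true_threshold_c, paste(signif(x$group_heat_log_rr, 3), collapse = ", ")))
  cat(sprintf("  temperature %.1f degC (SD %.2f, AR1 %.2f); %d scenarios, warming %.2f degC\n",
              x$temp_mean_c, x$temp_sd_c, x$temp_ar1, x$n_scenarios,
              x$scenario_warming_mean_c))
  invisible(x)
}

# fixed per-output-type seed offsets (documented contract: adding one output
# type never perturbs another)
seed_offsets <- c(weather = 11L, deaths = 22L, ensemble = 33L)

derive_seed <- function(seed, stream) {
  off <- seed_offsets[[stream]]
  as.integer((as.numeric(seed) + off) %% .Machine$integer.max)
}
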