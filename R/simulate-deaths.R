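# SES indicator bands (% of adults without a high-school diploma) backing the
# three designed terciles: a higher percentage means a more deprived area.
ses_bands <- function() {
  rbind(low  = c(200 / 3, 100),   # most deprived tercile
        mid  = c(100 / 3, 200 / 3),
        high = c(0, 100 / 3))     # most advantaged (reference) tercile
}

# expected YLL per death under the truncated-Gaussian age-at-death model with
# equal sex probability, by exact summation over the completed-age pmf
expected_yll_per_death <- function(config, life_table) {
  lo <- 35
  hi <- config$max_age
  z <- stats::pnorm(hi + 1, config$age_mean, config$age_sd) -
    stats::pnorm(lo, config$age_mean, config$age_sd)
  ages <- lo:hi
  p <- (stats::pnorm(pmin(ages + 1, hi + 1), config$age_mean, config$age_sd) -
          stats::pnorm(ages, config$age_mean, config$age_sd)) / z
  exf <- life_table$ex[life_table$sex == "female"][ages + 1]
  exm <- life_table$ex[life_table$sex == "male"][ages + 1]
  sum(p * (exf + exm) / 2)
}

#' Generate synthetic death records with a designed per-tercile heat effect
#'
#' For each day covered by `weather` and each SES tercile j, the death count is
#' Poisson with mean
#' `baseline_deaths_per_day * p_j * exp(beta_j * max(0, T_d - threshold))`,
#' so the heat effect acts multiplicatively on counts above the designed
#' threshold and is strongest in the most deprived tercile. Each record gets an
#' age at death (truncated Gaussian on [35, max_age], completed years), a sex
#' (equal probability) and an area SES indicator value drawn uniformly within
#' its tercile's band of the 0--100% indicator scale.
#'
#' @param config a [simulation_config()].
#' @param weather daily series from [generate_temperature_series()]; defines
#'   the simulated calendar.
#' @param life_table a [generate_life_table()] table (used for the
#'   ground-truth expected YLL bookkeeping).
#' @param seed RNG seed (default: death-stream seed derived from the master).
#' @return a data frame of death records (`date`, `age`, `sex`, `ses_value`)
#'   sorted by date, with attribute `ground_truth` recording the designed
#'   parameters and the expected per-tercile daily YLL at reference
#'   (below-threshold) temperatures.
#' @export
generate_deaths <- function(config, weather, life_table,
                            seed = derive_seed(config$seed, "deaths")) {
  validate_simulation_config(config)
  if (any(is.na(weather$temp_c))) {
    bad <- weather$date[which(is.na(weather$temp_c))[1]]
    stop("weather series has a missing temperature on ", format(bad), call. = FALSE)
  }
  if (anyDuplicated(weather$date))
    stop("weather series has duplicated dates", call. = FALSE)

  x <- pmax(weather$temp_c - config$true_threshold_c, 0)
  n_days <- nrow(weather)
  bands <- ses_bands()
  terciles <- rownames(bands)

  set.seed(seed)
  records <- vector("list", 3L)
  for (j in seq_len(3L)) {
    lambda <- config$baseline_deaths_per_day * config$ses_tercile_probs[j] *
      exp(config$group_heat_log_rr[[j]] * x)
    counts <- stats::rpois(n_days, lambda)
    n <- sum(counts)
    if (n == 0L) {
      records[[j]] <- data.frame(date = as.Date(character()), age = integer(),
                                 sex = character(), ses_value = numeric())
      next
    }
    # age: truncated Gaussian on [35, max_age] by inverse-CDF, completed years
    plo <- stats::pnorm(35, config$age_mean, config$age_sd)
    phi <- stats::pnorm(config$max_age + 1, config$age_mean, config$age_sd)
    age_cont <- stats::qnorm(stats::runif(n, plo, phi),
                             config$age_mean, config$age_sd)
    age <- pmin(as.integer(floor(age_cont)), config$max_age)
    records[[j]] <- data.frame(
      date = rep(weather$date, counts),
      age = age,
      sex = ifelse(stats::runif(n) < 0.5, "female", "male"),
      ses_value = stats::runif(n, bands[j, 1], bands[j, 2])
    )
  }
  out <- do.call(rbind, records)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL

  eyll <- expected_yll_per_death(config, life_table)
  gt_yll <- config$baseline_deaths_per_day * config$ses_tercile_probs * eyll
  names(gt_yll) <- terciles
  attr(out, "ground_truth") <- list(
    config = config,
    expected_yll_per_death = eyll,
    expected_daily_yll_at_reference = gt_yll
  )
  out
}

#' Generate a climate-scenario ensemble with known warming deltas
#'
#' Each scenario is a pair of daily summer temperature series from the same
#' sinusoid-plus-AR(1) family as the observed weather: the historical period
#' carries a scenario-specific mean bias (drawn from
#' `N(0, scenario_bias_sd_c^2)`, the miscalibration that quantile mapping must
#' remove) and the future period additionally adds a scenario-specific warming
#' delta drawn from `N(scenario_warming_mean_c, scenario_warming_sd_c^2)`.
#' Historical periods start in 1981, future periods in 2021.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (default: ensemble-stream seed derived from the
#'   master).
#' @return a `scenario_ensemble`: a list of `n_scenarios` elements, each with
#'   `scenario_id`, `historical` and `future` data frames (`date`, `temp_c`);
#'   attribute `ground_truth` records the drawn biases and warming deltas.
#' @export
generate_scenario_ensemble <- function(config,
                                       seed = derive_seed(config$seed, "ensemble")) {
  validate_simulation_config(config)
  set.seed(seed)
  k <- config$n_scenarios
  biases <- stats::rnorm(k, 0, config$scenario_bias_sd_c)
  deltas <- stats::rnorm(k, config$scenario_warming_mean_c,
                         config$scenario_warming_sd_c)
  subseeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * k), ncol = 2L)

  make_series <- function(mean_shift, sub_seed, start_year) {
    cfg <- config
    cfg$temp_mean_c <- config$temp_mean_c + mean_shift
    cfg$n_years <- config$scenario_years
    s <- generate_temperature_series(cfg, seed = sub_seed, start_year = start_year)
    s[, c("date", "temp_c")]
  }

  ensemble <- lapply(seq_len(k), function(s) {
    list(scenario_id = sprintf("scenario_%02d", s),
         historical = make_series(biases[s], subseeds[s, 1], 1981L),
         future = make_series(biases[s] + deltas[s], subseeds[s, 2], 2021L))
  })
  structure(ensemble,
            class = "scenario_ensemble",
            ground_truth = list(bias_c = biases, warming_delta_c = deltas))
}
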