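# Shared fixtures, built in code.

# small, fast study configuration for module tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_years = 6L, n_scenarios = 4L, scenario_years = 5L), list(...))
  do.call(simulation_config, args)
}

# one cached life table (quadrature is the slow part; the table is pure)
shared_life_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- generate_life_table(max_age = 100L, sex_gap_years = 4)
    tab
  }
})

# simulate a full observed study (weather + labelled deaths + daily series)
simulate_study <- function(config, seed = config$seed) {
  weather <- generate_temperature_series(config, seed = seed + 11L)
  lt <- shared_life_table()
  deaths <- generate_deaths(config, weather, lt, seed = seed + 22L)
  labeled <- assign_terciles(deaths)
  daily <- aggregate_daily(labeled, lt, weather$date)
  list(weather = weather, life_table = lt, deaths = deaths,
       daily = daily, dylld = dylld_series(daily))
}

# hand-rolled exposure-response fit object with known parameters, for
# closed-form checks that need no GLM
stub_fit <- function(threshold = 20, slope = log(1.25), period_mean = 50,
                     family = "quasi-poisson-log") {
  structure(list(threshold_c = threshold, log_rr_per_deg = slope,
                 slope_se = 0.01,
                 coef = c("(Intercept)" = log(period_mean), heat = slope),
                 coef_covariance = diag(c(1e-4, 1e-4)),
                 period_mean_dylld = period_mean,
                 n_days_used = 0L, n_days_above = NA_integer_,
                 fraction_floored = 0, warnings = character(),
                 family = family),
            class = "exposure_response_fit")
}

# small two-city configuration exercising every pipeline stage quickly
demo_pipeline_config <- function(out_dir, seed = 1L) {
  sim_a <- simulation_config(n_years = 4L, n_scenarios = 3L, scenario_years = 4L,
                             seed = 7L)
  sim_b <- simulation_config(n_years = 4L, n_scenarios = 3L, scenario_years = 4L,
                             temp_mean_c = 19.6, true_threshold_c = 22,
                             group_heat_log_rr = c(0.05, 0.025, 0.01),
                             seed = 8L)
  pipeline_config(
    cities = list(city_a = list(sim = sim_a, population = 1812723),
                  city_b = list(sim = sim_b, population = 2234105)),
    model = model_config(),
    out_dir = out_dir,
    seed = seed)
}

# minimal scenario-pair builder for projection tests
make_scenario <- function(id, hist_temp, fut_temp, start_hist = 1981L,
                          start_fut = 2021L) {
  n_h <- length(hist_temp)
  n_f <- length(fut_temp)
  list(scenario_id = id,
       historical = data.frame(
         date = summer_dates(ceiling(n_h / 92), 92L, start_hist)[seq_len(n_h)],
         temp_c = hist_temp),
       future = data.frame(
         date = summer_dates(ceiling(n_f / 92), 92L, start_fut)[seq_len(n_f)],
         temp_c = fut_temp))
}
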