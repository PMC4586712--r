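test_that("configuration invariants are enforced", {
  expect_error(simulation_config(ses_tercile_probs = c(0.5, 0.3, 0.1)),
               "sum to 1")
  expect_error(simulation_config(ses_tercile_probs = c(0.5, 0.5, 0)),
               "positive")
  expect_error(simulation_config(group_heat_log_rr = c(0.01, 0.03, 0.06)),
               "low-SES")
  expect_error(simulation_config(temp_ar1 = 1), "\\[0, 1\\)")
  expect_silent(validate_simulation_config(simulation_config()))
})

test_that("zero-noise temperatures equal the deterministic seasonal mean", {
  cfg <- quick_config(temp_ar1 = 0, temp_sd_c = 0)
  w <- generate_temperature_series(cfg, n_days = 184L, seed = 1)
  # independent recomputation of the centred sinusoid
  doy <- as.POSIXlt(w$date)$yday + 1
  raw <- cfg$seasonal_amplitude_c * cos(2 * pi * (doy - 196) / 365)
  window <- 152:(152 + cfg$days_per_summer - 1)
  cent <- mean(cfg$seasonal_amplitude_c * cos(2 * pi * (window - 196) / 365))
  expect_equal(w$temp_c, cfg$temp_mean_c + raw - cent, tolerance = 1e-12)
})

test_that("temperature series reproduces its designed moments", {
  cfg <- simulation_config(temp_mean_c = 20.4, temp_sd_c = 3.24, n_years = 18L)
  w <- generate_temperature_series(cfg, seed = 42)
  n <- nrow(w)
  phi <- cfg$temp_ar1
  se_mean <- sd(w$temp_c) * sqrt((1 + phi) / (1 - phi) / n)  # AR(1)-adjusted
  expect_lt(abs(mean(w$temp_c) - 20.4), 3 * se_mean)
  expect_lt(abs(sd(w$temp_c) - 3.24) / 3.24, 0.15)
})

test_that("generators are deterministic for a fixed seed", {
  cfg <- quick_config(seed = 5)
  expect_identical(generate_temperature_series(cfg, seed = 9),
                   generate_temperature_series(cfg, seed = 9))
  w <- generate_temperature_series(cfg, seed = 9)
  lt <- shared_life_table()
  d1 <- generate_deaths(cfg, w, lt, seed = 3)
  d2 <- generate_deaths(cfg, w, lt, seed = 3)
  expect_identical(d1, d2)
  expect_identical(generate_scenario_ensemble(cfg, seed = 4),
                   generate_scenario_ensemble(cfg, seed = 4))
})

test_that("life table is monotone, sex-gapped and matches a quadrature oracle", {
  lt <- shared_life_table()
  for (s in c("female", "male")) {
    ex <- lt$ex[lt$sex == s]
    expect_true(all(diff(ex) < 0))
    expect_gt(ex[length(ex)], 0)
  }
  e0 <- function(s) lt$ex[lt$sex == s & lt$age == 0]
  expect_equal(e0("female") - e0("male"), 4, tolerance = 1e-6)

  # brute-force trapezoid integration of the conditional survival curve
  gp <- attr(lt, "gompertz")
  t_grid <- seq(0, 70, by = 0.002)
  surv <- exp(-(gp[["a_male"]] / gp[["b"]]) *
                (exp(gp[["b"]] * (60 + t_grid)) - exp(gp[["b"]] * 60)))
  oracle_e60 <- sum((surv[-1] + surv[-length(surv)]) / 2 * diff(t_grid))
  expect_equal(lt$ex[lt$sex == "male" & lt$age == 60], oracle_e60,
               tolerance = 1e-5)
})

test_that("death counts are independent of temperature under a null heat effect", {
  cfg <- quick_config(group_heat_log_rr = c(0, 0, 0), baseline_deaths_per_day = 25)
  lt <- shared_life_table()
  n_seeds <- 40
  sig <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    w <- generate_temperature_series(cfg, seed = 1000 + i)
    d <- generate_deaths(cfg, w, lt, seed = 2000 + i)
    counts <- as.numeric(table(factor(as.character(d$date),
                                      levels = as.character(w$date))))
    heat <- pmax(w$temp_c - cfg$true_threshold_c, 0)
    p <- summary(lm(counts ~ heat))$coefficients["heat", "Pr(>|t|)"]
    sig[i] <- p < 0.05
  }
  expect_gte(mean(!sig), 0.85)  # nominal 95% of seeds should be null
})

test_that("degenerate and scale properties of the death generator hold", {
  cfg0 <- quick_config(baseline_deaths_per_day = 0)
  w <- generate_temperature_series(cfg0, n_days = 92L, seed = 1)
  lt <- shared_life_table()
  expect_identical(nrow(generate_deaths(cfg0, w, lt, seed = 1)), 0L)

  # large-city scale: ~37 deaths/day -> annual summer deaths near 3400
  cfg <- simulation_config(n_years = 4L, baseline_deaths_per_day = 37)
  totals <- vapply(1:3, function(i) {
    wi <- generate_temperature_series(cfg, seed = 100 + i)
    nrow(generate_deaths(cfg, wi, lt, seed = 200 + i)) / cfg$n_years
  }, numeric(1))
  expect_lt(abs(mean(totals) - 3400) / 3400, 0.10)

  # missing weather day is named
  w_bad <- w
  w_bad$temp_c[3] <- NA
  expect_error(generate_deaths(cfg0, w_bad, lt), format(w$date[3]))
})

test_that("SES values span [0,100] and tercile shares converge to the design", {
  cfg <- quick_config(ses_tercile_probs = c(0.5, 0.3, 0.2),
                      group_heat_log_rr = c(0.05, 0.02, 0))
  w <- generate_temperature_series(cfg, seed = 8)
  d <- generate_deaths(cfg, w, shared_life_table(), seed = 8)
  expect_true(all(d$ses_value >= 0 & d$ses_value <= 100))
  n <- nrow(d)
  bands <- rbind(low = c(200 / 3, 100), mid = c(100 / 3, 200 / 3), high = c(0, 100 / 3))
  for (j in 1:3) {
    share <- mean(d$ses_value > bands[j, 1] & d$ses_value <= bands[j, 2])
    p <- cfg$ses_tercile_probs[j]
    expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
  }
})

test_that("scenario ensemble realizes its designed warming and cardinality", {
  cfg <- quick_config(n_scenarios = 30L, scenario_years = 10L,
                      scenario_warming_sd_c = 0, scenario_warming_mean_c = 1.35)
  ens <- generate_scenario_ensemble(cfg, seed = 12)
  expect_length(ens, 30L)
  shift <- temperature_shift(ens)
  # the reported SE is i.i.d.-based; inflate for the AR(1) day-to-day
  # autocorrelation of both series when bounding the realized deltas
  infl <- sqrt((1 + cfg$temp_ar1) / (1 - cfg$temp_ar1))
  expect_true(all(abs(shift$delta_c - 1.35) < 4 * infl * shift$se))
  expect_lt(abs(mean(shift$delta_c) - 1.35), 0.1)
  gt <- attr(ens, "ground_truth")
  expect_length(gt$warming_delta_c, 30L)
  expect_equal(gt$warming_delta_c, rep(1.35, 30L))
})

test_that("zero-bias zero-warming scenarios are exchangeable with observations", {
  cfg <- quick_config(scenario_bias_sd_c = 0, scenario_warming_mean_c = 0,
                      scenario_warming_sd_c = 0, n_scenarios = 2L,
                      scenario_years = 10L)
  ok <- vapply(1:10, function(i) {
    ens <- generate_scenario_ensemble(cfg, seed = 300 + i)
    s <- ens[[1]]
    suppressWarnings(ks.test(s$future$temp_c, s$historical$temp_c)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
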