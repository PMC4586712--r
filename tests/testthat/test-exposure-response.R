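test_that("quasi-Poisson coefficients and covariance match an IRLS oracle", {
  cfg <- quick_config(n_years = 3L, seed = 17)
  st <- simulate_study(cfg)
  mc <- model_config(threshold_grid_quantiles = c(0.75, 0.75))  # one candidate
  fit <- fit_exposure_response(st$dylld, st$weather, mc)

  # independent iteratively-reweighted-least-squares implementation
  d <- fit$data
  d$dos <- as.integer(d$date - as.Date(sprintf("%d-06-01", d$year))) + 1L
  d$heat <- pmax(d$temp_c - fit$threshold_c, 0)
  X <- model.matrix(~ heat + splines::ns(dos, df = 3) + year + humidity_pct, d)
  y <- d$y
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  for (iter in 1:200) {
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
    w <- mu                      # quasi-Poisson log-link working weights
    z <- eta + (y - mu) / mu
    new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(new - beta)) < 1e-13) { beta <- as.numeric(new); break }
    beta <- as.numeric(new)
  }
  mu <- exp(as.numeric(X %*% beta))
  disp <- sum((y - mu)^2 / mu) / (length(y) - ncol(X))
  cov_o <- solve(t(X) %*% (mu * X)) * disp

  expect_equal(unname(fit$coef["heat"]), beta[2], tolerance = 1e-6)
  expect_equal(unname(fit$coef[1]), beta[1], tolerance = 1e-6)
  expect_equal(unname(fit$coef_covariance["heat", "heat"]), cov_o[2, 2],
               tolerance = 1e-6)
})

test_that("the relative-risk curve obeys its closed form and monotonicity", {
  fit <- stub_fit(threshold = 23, slope = 0.05)
  expect_equal(rr_curve(fit, 23), 1)
  expect_equal(rr_curve(fit, 20), 1)
  expect_equal(rr_curve(fit, 25), exp(0.1))
  grid <- seq(10, 35, by = 0.5)
  expect_true(all(diff(rr_curve(fit, grid)) >= 0))
})

test_that("attributable rates follow the attributable-fraction arithmetic", {
  # single hot day, RR = 1.25, observed DYLLD 100 -> 100 * 0.25/1.25 = 20
  fit <- stub_fit(threshold = 20, slope = log(1.25))
  w <- data.frame(date = as.Date("2001-06-01") + 0:1,
                  temp_c = c(19, 21), y = c(40, 100))
  res <- attributable_rate(fit, w, population = 1e5, mode = "observed-dylld",
                           n_draws = 50, seed = 1)
  expect_equal(res$rate, 20)

  # constant-baseline form: mean_DYLLD * (RR - 1)
  res2 <- attributable_rate(fit, w, population = 1e5, mode = "constant-baseline",
                            n_draws = 50, seed = 1)
  expect_equal(res2$rate, fit$period_mean_dylld * (1.25 - 1))

  # null effect -> exactly zero
  null_fit <- stub_fit(threshold = 20, slope = 0)
  res0 <- attributable_rate(null_fit, w, population = 1e5,
                            mode = "observed-dylld", n_draws = 10, seed = 1)
  expect_equal(res0$rate, 0)

  # doubling population halves the rate exactly
  res_half <- attributable_rate(fit, w, population = 2e5,
                                mode = "observed-dylld", n_draws = 50, seed = 1)
  expect_equal(res_half$rate, res$rate / 2)

  # no days above threshold -> zero with a warning
  cold <- data.frame(date = w$date, temp_c = c(10, 12), y = c(40, 100))
  expect_warning(res_c <- attributable_rate(fit, cold, population = 1e5,
                                            mode = "observed-dylld"),
                 "no days above")
  expect_equal(res_c$rate, 0)
  expect_equal(res_c$se, 0)
})

test_that("threshold selection is invariant to input row order", {
  cfg <- quick_config(n_years = 4L, seed = 23)
  st <- simulate_study(cfg)
  f1 <- fit_exposure_response(st$dylld, st$weather)
  set.seed(1)
  perm <- sample(nrow(st$dylld))
  f2 <- fit_exposure_response(st$dylld[perm, ], st$weather[sample(nrow(st$weather)), ])
  expect_equal(f1$deviance_profile, f2$deviance_profile)
  expect_equal(f1$threshold_c, f2$threshold_c)
  expect_equal(f1$log_rr_per_deg, f2$log_rr_per_deg)
})

test_that("a designed heat effect is recovered in direction and location", {
  cfg <- quick_config(n_years = 10L, seed = 29)
  st <- simulate_study(cfg)
  fit <- fit_exposure_response(st$dylld, st$weather)
  expect_gt(fit$log_rr_per_deg, 0)
  expect_lt(abs(fit$threshold_c - cfg$true_threshold_c), 2.5)
  expect_equal(fit$n_days_used, nrow(st$dylld))
})

test_that("dropping absent adjustment terms barely moves the slope", {
  cfg <- quick_config(n_years = 8L, seed = 31)
  st <- simulate_study(cfg)
  # same single candidate threshold for both fits, so only the adjustment
  # terms differ
  full <- fit_exposure_response(st$dylld, st$weather,
                                model_config(threshold_grid_quantiles = c(0.8, 0.8)))
  bare <- fit_exposure_response(st$dylld, st$weather,
                                model_config(humidity_term = "none",
                                             season_spline_df = 0L,
                                             year_trend = "none",
                                             threshold_grid_quantiles = c(0.8, 0.8)))
  expect_lt(abs(full$log_rr_per_deg - bare$log_rr_per_deg), full$slope_se)
})
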