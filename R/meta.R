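#' Random-effects pooling of per-scenario estimates
#'
#' DerSimonian-Laird pooling: the between-estimate variance tau^2 is the
#' method-of-moments value (floored at 0), weights are
#' `1 / (se^2 + tau^2)`, the pooled value is the weighted mean and its 95% CI
#' is normal-theory. Ratio measures such as the ICC should be pooled on the
#' log scale (see [pool_icc()]).
#'
#' @param estimates numeric vector of estimates (k >= 2).
#' @param ses positive standard errors, same length.
#' @return a `pooled_estimate` list: `pooled`, `se`, `ci`, `tau_squared`, `k`,
#'   `weights` (normalized), `q` (heterogeneity statistic).
#' @export
pool_estimates <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 2L) stop("need at least 2 estimates to pool", call. = FALSE)
  if (length(ses) != k || any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be positive", call. = FALSE)

  w_fe <- 1 / ses^2
  mu_fe <- sum(w_fe * estimates) / sum(w_fe)
  q <- sum(w_fe * (estimates - mu_fe)^2)
  c_dl <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
  tau2 <- max(0, (q - (k - 1)) / c_dl)

  w <- 1 / (ses^2 + tau2)
  pooled <- sum(w * estimates) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(0.975)
  structure(list(pooled = pooled, se = se,
                 ci = c(pooled - z * se, pooled + z * se),
                 tau_squared = tau2, k = k,
                 weights = w / sum(w), q = q),
            class = "pooled_estimate")
}

#' Pool impact-of-climate-change ratios
#'
#' Pools per-scenario ICC ratios on the log scale (where their sampling
#' distribution is closer to normal) and exponentiates the pooled value and
#' CI back to the ratio scale.
#'
#' @param icc positive ratio estimates.
#' @param log_se standard errors of `log(icc)`.
#' @return a `pooled_estimate` on the ratio scale, with `log_pooled` and
#'   `log_tau_squared` retained from the log-scale pooling.
#' @export
pool_icc <- function(icc, log_se) {
  if (any(icc <= 0)) stop("ICC estimates must be positive", call. = FALSE)
  p <- pool_estimates(log(icc), log_se)
  p$log_pooled <- p$pooled
  p$log_tau_squared <- p$tau_squared
  p$pooled <- exp(p$log_pooled)
  p$ci <- exp(p$ci)
  p$tau_squared <- p$log_tau_squared
  p
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (95%% CI %.4f to %.4f), k = %d, tau^2 = %.4g\n",
              x$pooled, x$ci[1], x$ci[2], x$k, x$tau_squared))
  invisible(x)
}

#' Compare two pooled estimates
#'
#' Two-sided z comparison of two independent pooled estimates on a common
#' scale, using their pooled standard errors.
#'
#' @param a,b `pooled_estimate` objects (same scale; for ICCs compare the
#'   log-scale pools).
#' @return list with `difference`, `se`, `z`, `p_value`, `ci`.
#' @export
compare_pooled <- function(a, b) {
  diff <- a$pooled - b$pooled
  se <- sqrt(a$se^2 + b$se^2)
  z <- if (se > 0) diff / se else 0
  zc <- stats::qnorm(0.975)
  list(difference = diff, se = se, z = z,
       p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1,
       ci = c(diff - zc * se, diff + zc * se))
}

#' Random-effects meta-regression on a binary city indicator
#'
#' Weighted least squares with DerSimonian-Laird-type method-of-moments
#' residual heterogeneity: a fixed-effect WLS fit gives the residual Q
#' statistic, tau^2 = max(0, (Q - (k - p)) / tr(P)) with
#' `P = W - W X (X'WX)^-1 X'W`, and the final coefficients are re-fit with
#' weights `1 / (se^2 + tau^2)`. The covariate is coded 0/1, so the city
#' coefficient is the adjusted between-city difference.
#'
#' @param estimates numeric outcomes (e.g. log future rates, or ICCs).
#' @param ses positive standard errors.
#' @param city binary indicator (0 = reference city, 1 = index city).
#' @return a `meta_regression` list: `beta_city`, `se`, `ci`, `p_value`,
#'   `k`, `residual_tau_squared`, `intercept`.
#' @export
meta_regress <- function(estimates, ses, city) {
  k <- length(estimates)
  if (k < 4L) stop("need at least 4 estimates for meta-regression", call. = FALSE)
  if (any(ses <= 0)) stop("all standard errors must be positive", call. = FALSE)
  city <- as.numeric(city)
  if (length(unique(city)) < 2L)
    stop("city indicator must have both levels present", call. = FALSE)

  x_mat <- cbind(1, city)
  p <- ncol(x_mat)
  w1 <- diag(1 / ses^2)
  xtw <- t(x_mat) %*% w1
  b1 <- solve(xtw %*% x_mat, xtw %*% estimates)
  resid <- estimates - as.numeric(x_mat %*% b1)
  q <- sum(diag(w1) * resid^2)
  p_mat <- w1 - t(xtw) %*% solve(xtw %*% x_mat, xtw)
  tau2 <- max(0, (q - (k - p)) / sum(diag(p_mat)))

  w2 <- diag(1 / (ses^2 + tau2))
  xtw2 <- t(x_mat) %*% w2
  vb <- solve(xtw2 %*% x_mat)
  b <- as.numeric(vb %*% xtw2 %*% estimates)
  se_b <- unname(sqrt(diag(vb)))
  z <- b[2] / se_b[2]
  zc <- stats::qnorm(0.975)
  structure(list(beta_city = b[2], se = se_b[2],
                 ci = c(b[2] - zc * se_b[2], b[2] + zc * se_b[2]),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 k = k, residual_tau_squared = tau2,
                 intercept = b[1]),
            class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("city effect %.4f (95%% CI %.4f to %.4f), p = %.3g, k = %d, residual tau^2 = %.4g\n",
              x$beta_city, x$ci[1], x$ci[2], x$p_value, x$k,
              x$residual_tau_squared))
  invisible(x)
}
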