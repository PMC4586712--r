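#!/usr/bin/env Rscript
# Pool the per-scenario estimates by random-effects meta-analysis within each
# city, then compare cities: pooled ICCs and warming, and meta-regressions of
# the 60 future rates (ln scale) and of the ICCs on the city indicator
# (index city coded 1).
source(file.path("analysis", "study_config.R"))

impacts <- list()
shifts <- list()
for (nm in names(study_cities())) {
  path <- file.path(tables_dir, paste0("04_impacts_", nm, ".csv"))
  if (!file.exists(path))
    stop("run analysis/04_projection.R first (missing ", path, ")")
  impacts[[nm]] <- read_with_meta(path, date_cols = character())
  shifts[[nm]] <- impacts[[nm]][, c("scenario_id", "warming_delta_c", "warming_se")]
}

rows <- list()
for (nm in names(impacts)) {
  ok <- !impacts[[nm]]$excluded
  picc <- pool_icc(impacts[[nm]]$icc[ok], impacts[[nm]]$log_icc_se[ok])
  pshift <- pool_estimates(shifts[[nm]]$warming_delta_c, shifts[[nm]]$warming_se)
  rows[[nm]] <- data.frame(
    city = nm, k = picc$k,
    pooled_icc = picc$pooled, icc_ci_lo = picc$ci[1], icc_ci_hi = picc$ci[2],
    icc_tau2_log = picc$tau_squared,
    pooled_warming_c = pshift$pooled,
    warming_ci_lo = pshift$ci[1], warming_ci_hi = pshift$ci[2])
  message(sprintf("%s: pooled ICC %.2f (95%% CI %.2f-%.2f), pooled warming %.2f degC",
                  nm, picc$pooled, picc$ci[1], picc$ci[2], pshift$pooled))
}
write_with_meta(do.call(rbind, rows), file.path(tables_dir, "05_pooled.csv"),
                meta = list(seed = study_seed))

a <- impacts$index_city
b <- impacts$reference_city
keep <- !a$excluded & !b$excluded
city_ind <- rep(c(1, 0), each = nrow(a))
y_rate <- log(c(a$future_rate, b$future_rate))
se_rate <- c(a$log_future_rate_se, b$log_future_rate_se)
mr_rate <- meta_regress(y_rate, se_rate, city_ind)
iccs <- c(a$icc, b$icc)
icc_ses <- c(a$log_icc_se, b$log_icc_se) * iccs
mr_icc <- meta_regress(iccs, icc_ses, city_ind)
cmp_shift <- compare_pooled(
  pool_estimates(shifts$index_city$warming_delta_c, shifts$index_city$warming_se),
  pool_estimates(shifts$reference_city$warming_delta_c, shifts$reference_city$warming_se))

contrast <- data.frame(
  contrast = c("icc_difference", "log_future_rate_ratio", "warming_difference_c"),
  estimate = c(mr_icc$beta_city, mr_rate$beta_city, cmp_shift$difference),
  ci_lo = c(mr_icc$ci[1], mr_rate$ci[1], cmp_shift$ci[1]),
  ci_hi = c(mr_icc$ci[2], mr_rate$ci[2], cmp_shift$ci[2]),
  p_value = c(mr_icc$p_value, mr_rate$p_value, cmp_shift$p_value))
write_with_meta(contrast, file.path(tables_dir, "05_between_city.csv"),
                meta = list(seed = study_seed))
message(sprintf(
  "between-city: ICC difference %.2f (p=%.2g); log future-rate ratio %.2f (p=%.2g); warming difference %.2f degC (p=%.2g)",
  mr_icc$beta_city, mr_icc$p_value, mr_rate$beta_city, mr_rate$p_value,
  cmp_shift$difference, cmp_shift$p_value))
message("wrote pooled and between-city tables under ", tables_dir)
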