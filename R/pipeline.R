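#' Pipeline configuration for an end-to-end synthetic study
#'
#' Bundles per-city simulation settings and populations with a shared model
#' configuration, an output directory and a master seed. The first configured
#' city is the index city (coded 1) in the between-city meta-regression.
#'
#' @param cities named list; each element is a list with `sim` (a
#'   [simulation_config()]) and `population` (persons at risk).
#' @param model a [model_config()].
#' @param out_dir directory for all artifacts (created if needed).
#' @param seed master seed for the analysis stages (attribution and
#'   projection draws); each city's simulation uses its own `sim$seed`.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(cities, model = model_config(), out_dir, seed = 1L) {
  cfg <- structure(list(cities = cities, model = model,
                        out_dir = out_dir, seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!length(cfg$cities) || is.null(names(cfg$cities)) ||
      any(!nzchar(names(cfg$cities))))
    stop("cities must be a non-empty named list", call. = FALSE)
  for (nm in names(cfg$cities)) {
    ct <- cfg$cities[[nm]]
    if (is.null(ct$sim)) stop("city '", nm, "' lacks a simulation config", call. = FALSE)
    validate_simulation_config(ct$sim)
    if (is.null(ct$population) || !is.numeric(ct$population) || ct$population <= 0)
      stop("city '", nm, "' needs a positive population", call. = FALSE)
    if (!is.null(ct$lifetable_path) && !file.exists(ct$lifetable_path))
      stop("city '", nm, "' life-table path does not exist: ",
           ct$lifetable_path, call. = FALSE)
  }
  if (!inherits(cfg$model, "model_config"))
    stop("model must be a model_config()", call. = FALSE)
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir))
    stop("out_dir must be set", call. = FALSE)
  cfg
}

config_hash <- function(cfg) {
  core <- cfg[setdiff(names(cfg), "out_dir")]  # hash the science, not the location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(core, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full disparity pipeline for every configured city
#'
#' Stages per city: simulate weather, life table and deaths; aggregate daily
#' YLL by SES tercile; form the daily disparity series; fit the
#' threshold exposure-response model; estimate the historical attributable
#' rate; simulate the climate-scenario ensemble and compute per-scenario
#' impacts; pool ICCs and temperature shifts. With two or more cities a final
#' meta stage compares pooled ICCs and runs the meta-regressions on log future
#' rates and on ICCs. Every artifact is plain text with a metadata header and
#' is listed, with its MD5 hash, in `manifest.tsv`; the run is deterministic
#' for a fixed configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress to stderr.
#' @return invisibly, a list with `manifest` (data frame of file, md5) and
#'   `summary` (per-city and meta results).
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  files <- character()
  meta_for <- function(extra = list()) {
    c(list(package_version = as.character(utils::packageVersion("dylld")),
           config_hash = hash, seed = cfg$seed), extra)
  }
  emit <- function(x, name, writer = write_with_meta, extra = list()) {
    path <- file.path(cfg$out_dir, name)
    writer(x, path, meta = meta_for(extra))
    files <<- c(files, path)
    path
  }

  city_results <- list()
  for (nm in names(cfg$cities)) {
    ct <- cfg$cities[[nm]]
    sim <- ct$sim
    say(nm, ": simulate")
    weather <- generate_temperature_series(sim)
    lt <- if (!is.null(ct$lifetable_path)) read_life_table(ct$lifetable_path)
          else generate_life_table(max_age = sim$max_age)
    deaths <- generate_deaths(sim, weather, lt)
    if (!is.null(ct$min_age)) deaths <- deaths[deaths$age > ct$min_age, , drop = FALSE]
    emit(weather, paste0(nm, "_weather.csv"), extra = list(city = nm))
    emit(as.data.frame(lt), paste0(nm, "_lifetable.csv"), extra = list(city = nm))
    emit(deaths, paste0(nm, "_deaths.csv"), extra = list(city = nm))

    say(nm, ": daily YLL and disparity")
    labeled <- assign_terciles(deaths)
    daily <- aggregate_daily(labeled, lt, weather$date)
    dy <- dylld_series(daily, reference = "high")
    emit(daily, paste0(nm, "_daily_yll.csv"), extra = list(city = nm))
    emit(dy, paste0(nm, "_dylld.csv"), extra = list(city = nm))

    say(nm, ": exposure-response fit")
    fit <- fit_exposure_response(dy, weather, cfg$model)
    emit(fit, paste0(nm, "_fit.txt"), writer = write_fit, extra = list(city = nm))

    say(nm, ": attribution and projection")
    hist_rate <- attributable_rate(fit, population = ct$population,
                                   mode = "observed-dylld",
                                   seed = cfg$seed + 101L)
    ensemble <- generate_scenario_ensemble(sim)
    impacts <- scenario_impacts(fit, ensemble, weather, ct$population,
                                seed = cfg$seed + 202L)
    shifts <- temperature_shift(ensemble)
    emit(impacts, paste0(nm, "_scenario_impacts.csv"), extra = list(city = nm))
    emit(shifts, paste0(nm, "_temperature_shift.csv"), extra = list(city = nm))

    ok <- !impacts$excluded
    pooled_icc <- pool_icc(impacts$icc[ok], impacts$log_icc_se[ok])
    pooled_shift <- pool_estimates(shifts$delta_c, shifts$se)
    city_results[[nm]] <- list(
      fit = fit, hist_rate = hist_rate, impacts = impacts, shifts = shifts,
      pooled_icc = pooled_icc, pooled_shift = pooled_shift,
      population = ct$population)

    emit(data.frame(
      quantity = c("threshold_c", "log_rr_per_deg",
                   "historical_attributable_rate", "historical_rate_ci_lo",
                   "historical_rate_ci_hi", "pooled_icc", "pooled_icc_ci_lo",
                   "pooled_icc_ci_hi", "pooled_temp_shift_c"),
      value = c(fit$threshold_c, fit$log_rr_per_deg, hist_rate$rate,
                hist_rate$ci[1], hist_rate$ci[2], pooled_icc$pooled,
                pooled_icc$ci[1], pooled_icc$ci[2], pooled_shift$pooled)),
      paste0(nm, "_summary.csv"), extra = list(city = nm))
  }

  meta_res <- NULL
  if (length(city_results) >= 2L) {
    say("meta: between-city comparison")
    nms <- names(city_results)
    a <- city_results[[nms[1]]]
    b <- city_results[[nms[2]]]
    icc_cmp <- compare_pooled(
      pool_estimates(log(a$impacts$icc[!a$impacts$excluded]),
                     a$impacts$log_icc_se[!a$impacts$excluded]),
      pool_estimates(log(b$impacts$icc[!b$impacts$excluded]),
                     b$impacts$log_icc_se[!b$impacts$excluded]))
    shift_cmp <- compare_pooled(a$pooled_shift, b$pooled_shift)

    ests <- c(a$impacts$future_rate, b$impacts$future_rate)
    ses <- c(a$impacts$log_future_rate_se, b$impacts$log_future_rate_se)
    city <- rep(c(1, 0), times = c(nrow(a$impacts), nrow(b$impacts)))
    keep <- c(!a$impacts$excluded, !b$impacts$excluded) & ests > 0
    mr_rate <- meta_regress(log(ests[keep]), ses[keep], city[keep])
    iccs <- c(a$impacts$icc, b$impacts$icc)
    # identity-scale ICC standard errors by the delta method
    icc_ses <- c(a$impacts$log_icc_se, b$impacts$log_icc_se) * iccs
    mr_icc <- meta_regress(iccs[keep], icc_ses[keep], city[keep])

    meta_res <- list(icc_comparison = icc_cmp, shift_comparison = shift_cmp,
                     meta_regression_log_rate = mr_rate,
                     meta_regression_icc = mr_icc,
                     index_city = nms[1], reference_city = nms[2])
    emit(data.frame(
      quantity = c("log_icc_difference", "log_icc_diff_p",
                   "temp_shift_difference_c", "temp_shift_p",
                   "beta_city_log_future_rate", "beta_city_log_rate_p",
                   "beta_city_icc", "beta_city_icc_ci_lo", "beta_city_icc_ci_hi"),
      value = c(icc_cmp$difference, icc_cmp$p_value, shift_cmp$difference,
                shift_cmp$p_value, mr_rate$beta_city, mr_rate$p_value,
                mr_icc$beta_city, mr_icc$ci[1], mr_icc$ci[2])),
      "meta_summary.csv")
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("wrote ", nrow(manifest), " artifacts to ", cfg$out_dir)
  invisible(list(manifest = manifest,
                 summary = list(cities = city_results, meta = meta_res)))
}
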