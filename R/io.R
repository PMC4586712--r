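# Plain-text I/O: every artifact is a headered CSV (or key/value document)
# preceded by '#'-prefixed metadata lines (package version, config hash, seed)
# so each stage can be inspected and re-run on its own.

meta_lines <- function(meta) {
  vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), character(1))
}

#' Write a delimited artifact with a metadata header block
#'
#' @param x data frame to write.
#' @param path output file.
#' @param meta named list of metadata (written as `# key: value` lines).
#' @return `path`, invisibly.
#' @export
write_with_meta <- function(x, path, meta = list()) {
  x <- as.data.frame(x)
  for (col in names(x)) if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(meta_lines(meta), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delimited artifact written by [write_with_meta()]
#'
#' @param path file to read.
#' @param date_cols columns to parse as `Date`.
#' @return a data frame; metadata lines are attached as attribute `meta`.
#' @export
read_with_meta <- function(path, date_cols = "date") {
  head_lines <- readLines(path, n = 50L)
  meta <- grep("^# ", head_lines, value = TRUE)
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in intersect(date_cols, names(x))) x[[col]] <- as.Date(x[[col]])
  attr(x, "meta") <- sub("^# ", "", meta)
  x
}

#' Read a life table from delimited text
#'
#' Expects columns `sex`, `age`, `ex` covering ages 0..max for both sexes.
#'
#' @param path CSV file.
#' @return a `life_table` data frame.
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sex", "age", "ex")
  if (!all(need %in% names(x)))
    stop("life table file must have columns sex, age, ex", call. = FALSE)
  structure(x[need], class = c("life_table", "data.frame"),
            max_age = max(x$age))
}

#' Write an exposure-response fit as a structured text document
#'
#' Key/value lines for the scalar results, then the coefficient vector,
#' covariance matrix and deviance profile as labelled blocks.
#'
#' @param fit an `exposure_response_fit`.
#' @param path output file.
#' @param meta named metadata list.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, meta = list()) {
  num <- function(v) sprintf("%.17g", v)
  lines <- c(
    meta_lines(meta),
    paste0("family: ", fit$family),
    paste0("threshold_c: ", num(fit$threshold_c)),
    paste0("log_rr_per_deg: ", num(fit$log_rr_per_deg)),
    paste0("slope_se: ", num(fit$slope_se)),
    paste0("period_mean_dylld: ", num(fit$period_mean_dylld)),
    paste0("n_days_used: ", fit$n_days_used),
    paste0("n_days_above: ", fit$n_days_above),
    paste0("fraction_floored: ", num(fit$fraction_floored)),
    paste0("warnings: ", if (length(fit$warnings)) paste(fit$warnings, collapse = "; ") else "none"),
    "",
    "[coefficients]",
    paste(names(fit$coef), num(fit$coef), sep = "\t"),  # names may contain commas
    "",
    "[covariance]",
    apply(fit$coef_covariance, 1, function(r) paste(num(r), collapse = ",")),
    "",
    "[deviance_profile]",
    "threshold_c,deviance",
    paste(num(fit$deviance_profile$threshold_c),
          num(fit$deviance_profile$deviance), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an exposure-response fit written by [write_fit()]
#'
#' Restores the scalar results, coefficient vector, covariance matrix and
#' deviance profile. The day-level fitting data are not stored in the text
#' document, so a re-read fit supports [rr_curve()], constant-baseline
#' [attributable_rate()] and [scenario_impacts()], but observed-disparity
#' attribution needs a weather series carrying the disparity column.
#'
#' @param path file produced by [write_fit()].
#' @return an `exposure_response_fit` (without the `data` element).
#' @export
read_fit <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  val <- function(key) {
    row <- grep(paste0("^", key, ": "), lines, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", row)
  }
  block <- function(name) {
    start <- which(lines == paste0("[", name, "]")) + 1L
    stop_at <- c(which(lines == ""), length(lines) + 1L)
    end <- min(stop_at[stop_at >= start]) - 1L
    lines[start:end]
  }
  coef_rows <- strsplit(block("coefficients"), "\t", fixed = TRUE)
  cf <- stats::setNames(vapply(coef_rows, function(r) as.numeric(r[2]), numeric(1)),
                        vapply(coef_rows, `[`, character(1), 1))
  cov <- do.call(rbind, lapply(strsplit(block("covariance"), ",", fixed = TRUE),
                               as.numeric))
  dimnames(cov) <- list(names(cf), names(cf))
  prof <- do.call(rbind, lapply(strsplit(block("deviance_profile")[-1], ",", fixed = TRUE),
                                as.numeric))
  structure(list(
    threshold_c = as.numeric(val("threshold_c")),
    log_rr_per_deg = as.numeric(val("log_rr_per_deg")),
    slope_se = as.numeric(val("slope_se")),
    coef = cf,
    coef_covariance = cov,
    period_mean_dylld = as.numeric(val("period_mean_dylld")),
    deviance_profile = data.frame(threshold_c = prof[, 1], deviance = prof[, 2]),
    n_days_used = as.integer(val("n_days_used")),
    n_days_above = as.integer(val("n_days_above")),
    fraction_floored = as.numeric(val("fraction_floored")),
    warnings = if (identical(val("warnings"), "none")) character()
               else strsplit(val("warnings"), "; ", fixed = TRUE)[[1]],
    family = val("family")
  ), class = "exposure_response_fit")
}
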