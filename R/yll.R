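#' Years of life lost for death records
#'
#' Looks up, for each death, the remaining life expectancy at the sex and
#' completed age at death in a single-year life table (no interpolation): the
#' standard years-of-life-lost weight for one death.
#'
#' @param records a data frame of death records with columns `age` and `sex`.
#' @param table a `life_table` from [generate_life_table()] or
#'   [read_life_table()].
#' @return a numeric vector of YLL (years), one per record.
#' @export
compute_yll <- function(records, table) {
  max_age <- attr(table, "max_age")
  if (is.null(max_age)) max_age <- max(table$age)
  bad <- which(records$age < 0 | records$age > max_age)
  if (length(bad)) {
    stop(sprintf("record %d (date %s, age %d) is outside the life table range 0..%d",
                 bad[1], format(records$date[bad[1]]), records$age[bad[1]], max_age),
         call. = FALSE)
  }
  key <- paste(records$sex, records$age)
  tab_key <- paste(table$sex, table$age)
  idx <- match(key, tab_key)
  if (anyNA(idx)) stop("life table does not cover every (sex, age) present", call. = FALSE)
  table$ex[idx]
}

#' Assign SES terciles to death records
#'
#' Splits records at the 1/3 and 2/3 empirical quantiles (inverse-CDF, type 1)
#' of the area SES indicator over all deaths (deaths-weighted, full period).
#' The indicator is % without a high-school diploma, so higher values mean
#' lower SES: records at or below the first cut are the most advantaged
#' ("high" SES, the reference group), records above the second cut the most
#' deprived ("low"). Values tied with a cut go to the less-deprived group.
#'
#' @param records a data frame with a `ses_value` column in [0, 100].
#' @return `records` with an added `tercile` factor (levels low, mid, high).
#' @export
assign_terciles <- function(records) {
  v <- records$ses_value
  if (length(v) < 3L || length(unique(v)) < 2L)
    stop("terciles are undefined: need >= 3 records with non-identical ses_value",
         call. = FALSE)
  cuts <- stats::quantile(v, c(1, 2) / 3, type = 1, names = FALSE)
  tercile <- ifelse(v <= cuts[1], "high", ifelse(v <= cuts[2], "mid", "low"))
  records$tercile <- factor(tercile, levels = c("low", "mid", "high"))
  attr(records, "tercile_cuts") <- cuts
  records
}

#' Aggregate YLL by day and SES tercile
#'
#' Sums individual YLL over each calendar day, in total and within each SES
#' tercile, keeping zero-death days as explicit zeros so the series is complete
#' for time-series modelling. The total is accumulated directly from all
#' records (not as the sum of tercile columns), so tercile/total conservation
#' is a checkable property, not an identity of the code path.
#'
#' @param records tercile-labelled death records (see [assign_terciles()]).
#' @param table a `life_table`.
#' @param calendar `Date` vector of all days the series must cover.
#' @return a data frame with one row per calendar day: `date`, `yll_total`,
#'   `yll_low`, `yll_mid`, `yll_high`, `n_low`, `n_mid`, `n_high`.
#' @export
aggregate_daily <- function(records, table, calendar) {
  calendar <- sort(unique(calendar))
  if (nrow(records) > 0 && !all(records$date %in% calendar)) {
    bad <- records$date[!records$date %in% calendar][1]
    stop("death record dated ", format(bad), " falls outside the calendar",
         call. = FALSE)
  }
  if (is.null(records$tercile))
    stop("records must be tercile-labelled; run assign_terciles() first", call. = FALSE)

  yll <- if (nrow(records)) compute_yll(records, table) else numeric(0)
  day <- factor(as.character(records$date), levels = as.character(calendar))
  sum_by <- function(values, subset) {
    as.numeric(tapply(values[subset], day[subset], sum, default = 0))
  }
  out <- data.frame(date = calendar,
                    yll_total = sum_by(yll, rep(TRUE, length(yll))))
  for (g in c("low", "mid", "high")) {
    sel <- records$tercile == g
    out[[paste0("yll_", g)]] <- sum_by(yll, sel)
    out[[paste0("n_", g)]] <- as.integer(sum_by(rep(1, length(yll)), sel))
  }
  out
}
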