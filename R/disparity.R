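#' Daily years-of-life-lost disparity for one day
#'
#' The disparity index for a day is the mean, over the non-reference SES
#' groups, of that group's daily YLL minus the reference group's daily YLL:
#' a single number summarizing how much extra burden the less advantaged
#' groups carry that day. It is negative when the reference group has the
#' higher burden; negative values are preserved here (how the exposure model
#' handles them is its own, documented choice).
#'
#' @param day_values named numeric vector of per-group daily YLL.
#' @param reference name of the reference (most advantaged) group.
#' @return the disparity (years).
#' @export
compute_dylld <- function(day_values, reference = "high") {
  if (!reference %in% names(day_values))
    stop("unknown reference group '", reference, "'", call. = FALSE)
  others <- day_values[setdiff(names(day_values), reference)]
  if (!length(others)) stop("need at least one non-reference group", call. = FALSE)
  mean(others - day_values[[reference]])
}

#' Daily disparity series from stratified daily YLL
#'
#' Applies [compute_dylld()] to every day of an [aggregate_daily()] series,
#' with the most advantaged tercile as the reference.
#'
#' @param daily a daily stratified YLL series (columns `yll_low`, `yll_mid`,
#'   `yll_high`).
#' @param reference reference tercile (default "high", the most advantaged).
#' @return a data frame `date`, `dylld` (years), `dyll_ref` (reference-group
#'   daily YLL, years).
#' @export
dylld_series <- function(daily, reference = "high") {
  if (!nrow(daily)) stop("daily series is empty", call. = FALSE)
  groups <- c("low", "mid", "high")
  if (!reference %in% groups)
    stop("unknown reference group '", reference, "'", call. = FALSE)
  ref <- daily[[paste0("yll_", reference)]]
  others <- setdiff(groups, reference)
  diffs <- do.call(cbind, lapply(others, function(g) daily[[paste0("yll_", g)]] - ref))
  data.frame(date = daily$date,
             dylld = rowMeans(diffs),
             dyll_ref = ref)
}
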