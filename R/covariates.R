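#' Derive history control covariates from raw decision records
#'
#' Recomputes, strictly from each user's past, the six control
#' covariates used by the excursion-effect analyses: `week_in_study`
#' (0 for days 1-7, 1 for days 8-14, ...), `which_day` (1 Monday-Friday,
#' 0 weekend), `days_since_chart` (days since the last chart before the
#' current day, capped at 30; days since enrollment if the user never
#' charted), `pushed_indicator` (any push sent in the past),
#' `push_success_ratio` (past pushes followed by a chart within the
#' 24-hour window, divided by past pushes; 0 if none sent) and
#' `has_charted_10` (at least 10 past charts, the app's insights-unlock
#' threshold).
#'
#' Chart events are reconstructed at day resolution from `outcome_24h`
#' (all slots of a day share the day's chart indicator), matching the
#' simulator's convention.  No covariate looks at the current day's
#' outcome.
#'
#' @param records A decision-record `data.frame` ordered by `user_id`,
#'   `day`, `slot` (unordered input is an error, not silently fixed).
#' @param config The [trial_config()] supplying the calendar anchor for
#'   `which_day`.
#' @return `records` with the six covariate columns (re)computed.
#' @export
derive_covariates <- function(records, config = trial_config()) {
  need <- c("user_id", "day", "slot", "considered", "push", "outcome_24h")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ord <- order(records$user_id, records$day, records$slot)
  if (!identical(ord, seq_len(nrow(records))))
    stop("records must be ordered by user_id, day, slot", call. = FALSE)

  # day-level event table
  key <- paste(records$user_id, records$day)
  first <- !duplicated(key)
  du <- records$user_id[first]
  dd <- records$day[first]
  chart <- as.numeric(tapply(records$outcome_24h, key, max)[unique(key)])
  pushed <- as.numeric(tapply(records$push, key, max)[unique(key)])
  success <- as.numeric(pushed == 1 & chart == 1)

  lag0 <- function(x) c(0, x[-length(x)])
  cum_before <- function(x, u) stats::ave(x, u, FUN = function(z) lag0(cumsum(z)))
  last_chart_before <- stats::ave(ifelse(chart == 1, dd, 0), du,
                                  FUN = function(z) lag0(cummax(z)))
  pushes_before <- cum_before(pushed, du)
  success_before <- cum_before(success, du)
  charts_before <- cum_before(chart, du)

  day_cov <- data.frame(
    key = paste(du, dd),
    week_in_study = (dd - 1L) %/% 7L,
    which_day = as.integer(!is_weekend_day(config, dd)),
    days_since_chart = pmin(ifelse(last_chart_before == 0, dd - 1,
                                   dd - last_chart_before), 30),
    pushed_indicator = as.integer(pushes_before > 0),
    push_success_ratio = ifelse(pushes_before > 0,
                                success_before / pushes_before, 0),
    has_charted_10 = as.integer(charts_before >= 10))

  i <- match(key, day_cov$key)
  for (v in setdiff(names(day_cov), "key")) records[[v]] <- day_cov[[v]][i]
  records
}
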