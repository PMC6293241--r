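#' Inactivity-based availability rule table
#'
#' The trial throttles notification frequency by longitudinal
#' disengagement: the longer a user has been inactive, the more days the
#' system waits after a previous notification decision before the user
#' becomes available again.  The default buckets are
#' `[0,2) -> 3`, `[2,10) -> 2`, `[10,30) -> 6`, `[30,Inf) -> 15` days.
#'
#' @param breaks Numeric vector of left bucket edges, starting at 0 and
#'   strictly increasing.  Bucket `i` covers `[breaks[i], breaks[i+1])`;
#'   the last bucket is open-ended.
#' @param wait_days Integer vector, one wait (in days, >= 1) per bucket.
#' @return An object of class `availability_rules`.
#' @examples
#' rules <- availability_rules()
#' wait_days(rules, 5)   # 2
#' @export
availability_rules <- function(breaks = c(0, 2, 10, 30),
                               wait_days = c(3, 2, 6, 15)) {
  if (length(breaks) != length(wait_days))
    stop("`breaks` and `wait_days` must have the same length", call. = FALSE)
  if (breaks[1] != 0)
    stop("first bucket must start at 0 so the buckets partition [0, Inf)",
         call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("`breaks` must be strictly increasing", call. = FALSE)
  if (any(wait_days < 1))
    stop("all waits must be >= 1 day", call. = FALSE)
  structure(list(breaks = as.numeric(breaks),
                 wait_days = as.numeric(wait_days)),
            class = "availability_rules")
}

#' Days to wait before the next notification decision
#'
#' Looks up the bucket of the rule table containing `days_inactive` and
#' returns its wait.  Vectorised over `days_inactive`.
#'
#' @param rules An [availability_rules()] table.
#' @param days_inactive Nonnegative number of days since the user last
#'   engaged (charted) with the app.
#' @return Wait in days (same length as `days_inactive`).
#' @export
wait_days <- function(rules, days_inactive) {
  stopifnot(inherits(rules, "availability_rules"))
  if (any(days_inactive < 0))
    stop("`days_inactive` must be nonnegative", call. = FALSE)
  idx <- findInterval(days_inactive, rules$breaks)
  rules$wait_days[idx]
}

#' Trial design configuration
#'
#' Describes the decision-point grid of the micro-randomized trial: study
#' length, the daily slot schedule, the randomization probability at a
#' considered decision point, the availability rule table, and the
#' weekend-morning exclusion.
#'
#' @param n_days Number of study days (default 89).
#' @param slot_times Ordered character vector of daily decision times
#'   (`"HH:MM"`, 24h clock).  Default: 08:30, 12:30, 17:30, 18:30,
#'   19:30, 20:30.
#' @param randomization_prob Probability of sending a push at a
#'   considered decision point; must lie strictly in (0, 1).  Default 0.5.
#' @param rules An [availability_rules()] table.
#' @param weekend_morning_blocked If `TRUE` (default) no decision slot
#'   before noon is open on Saturdays or Sundays.
#' @param start_weekday Day-of-week of study day 1, `1` = Monday ...
#'   `7` = Sunday.  Default 1.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_days = 89,
                         slot_times = c("08:30", "12:30", "17:30",
                                        "18:30", "19:30", "20:30"),
                         randomization_prob = 0.5,
                         rules = availability_rules(),
                         weekend_morning_blocked = TRUE,
                         start_weekday = 1L) {
  problems <- character(0)
  mins <- slot_minutes(slot_times)
  if (anyNA(mins))
    problems <- c(problems, "`slot_times` must be HH:MM clock times")
  else if (any(diff(mins) <= 0))
    problems <- c(problems, "`slot_times` must be strictly increasing within the day")
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1)
    problems <- c(problems, "`n_days` must be a single integer >= 1")
  if (!is.numeric(randomization_prob) || length(randomization_prob) != 1L ||
      randomization_prob <= 0 || randomization_prob >= 1)
    problems <- c(problems, "`randomization_prob` must lie strictly in (0, 1)")
  if (!inherits(rules, "availability_rules"))
    problems <- c(problems, "`rules` must be an availability_rules() table")
  if (!start_weekday %in% 1:7)
    problems <- c(problems, "`start_weekday` must be in 1..7 (1 = Monday)")
  if (length(problems))
    stop(paste(c("invalid trial configuration:", paste0("  - ", problems)),
               collapse = "\n"), call. = FALSE)
  structure(list(n_days = as.integer(n_days),
                 slot_times = slot_times,
                 slot_minutes = mins,
                 randomization_prob = randomization_prob,
                 rules = rules,
                 weekend_morning_blocked = isTRUE(weekend_morning_blocked),
                 start_weekday = as.integer(start_weekday)),
            class = "trial_config")
}

slot_minutes <- function(times) {
  m <- regmatches(times, regexec("^([0-9]{1,2}):([0-9]{2})$", times))
  vapply(m, function(x) {
    if (length(x) != 3L) return(NA_real_)
    as.numeric(x[2]) * 60 + as.numeric(x[3])
  }, numeric(1))
}

#' Day-of-week and weekend helpers for a study day index
#'
#' @param config A [trial_config()].
#' @param day_index Study day, 1-based.
#' @return `weekday_of()` returns 1..7 (1 = Monday); `is_weekend_day()`
#'   returns `TRUE` for Saturday/Sunday.  Both are vectorised.
#' @keywords internal
weekday_of <- function(config, day_index) {
  ((config$start_weekday - 1L + as.integer(day_index) - 1L) %% 7L) + 1L
}

#' @rdname weekday_of
#' @keywords internal
is_weekend_day <- function(config, day_index) {
  weekday_of(config, day_index) >= 6L
}

#' True outcome-model parameters for the synthetic generator
#'
#' The synthetic cohort draws the binary chart-within-24h outcome from a
#' log-linear model: the daily chart probability is
#' `min(prob_cap, exp(g' alpha + b_u + A * f' beta))` where `g` is the
#' control covariate vector (intercept, week in study, days since chart,
#' pushed indicator, pushed x success ratio, has-charted-10), `b_u` a
#' per-user Normal(0, user_sd^2) intercept, `A` the push indicator at the
#' day's considered decision point and `f` the moderator vector.
#'
#' @param alpha Named numeric vector of true control coefficients.  The
#'   default gives an untreated daily chart probability of roughly 0.25
#'   for a recently-active user.
#' @param beta Numeric vector of true excursion coefficients on the log
#'   risk-ratio scale (matching `moderators`); default a marginal effect
#'   of 0.04.
#' @param moderators Character vector naming the moderator columns the
#'   data-generating `f` is built from (intercept always included);
#'   default none, i.e. `f = 1`.
#' @param user_sd Standard deviation of the per-user intercept (log
#'   scale); default 0.3.
#' @param prob_cap Upper cap applied to the log-linear mean so it stays a
#'   probability; default 0.95.
#' @param hidden_weekend_uplift Log-scale uplift added on weekend days by
#'   the generator but never available to the analysis model; default 0
#'   (off).  See [misspecified_variant()].
#' @return An object of class `outcome_params`.
#' @export
outcome_params <- function(alpha = c(intercept = -1.25,
                                     week_in_study = 0,
                                     days_since_chart = -0.03,
                                     pushed_indicator = -0.1,
                                     push_success_ratio = 0.2,
                                     has_charted_10 = 0.2),
                           beta = c(intercept = 0.04),
                           moderators = character(0),
                           user_sd = 0.3,
                           prob_cap = 0.95,
                           hidden_weekend_uplift = 0) {
  if (user_sd < 0) stop("`user_sd` must be >= 0", call. = FALSE)
  if (prob_cap <= 0 || prob_cap >= 1)
    stop("`prob_cap` must lie strictly in (0, 1)", call. = FALSE)
  if (length(beta) != length(moderators) + 1L)
    stop("`beta` must have one entry per moderator plus the intercept",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta, moderators = moderators,
                 user_sd = user_sd, prob_cap = prob_cap,
                 hidden_weekend_uplift = hidden_weekend_uplift),
            class = "outcome_params")
}

#' Hide a true control covariate from the analysis model
#'
#' Returns a copy of `params` whose data-generating control model adds a
#' weekend uplift that the analysis control vector `g` does not contain.
#' The excursion coefficients are untouched, so the variant exercises the
#' estimator's robustness to nuisance-model misspecification.
#'
#' @param params An [outcome_params()] object.
#' @param weekend_uplift Log-scale coefficient of the hidden weekend
#'   indicator (default 0.3).
#' @return An `outcome_params` object.
#' @export
misspecified_variant <- function(params, weekend_uplift = 0.3) {
  stopifnot(inherits(params, "outcome_params"))
  params$hidden_weekend_uplift <- weekend_uplift
  params
}

#' Synthetic cohort configuration
#'
#' Population size and baseline-trait mix for the simulated cohort.  The
#' default trait shares mirror a workplace well-being app population:
#' 63.97% female, age buckets (<30 / 30-50 / >50) 28.86/42.44/28.70%, and
#' 52.88% with BMI >= 25.  Traits are fixture dressing only: they do not
#' enter the outcome model.
#'
#' @param n_users Number of users (default 1255).
#' @param share_female Proportion female.
#' @param age_shares Length-3 proportions for age buckets `<30`, `30-50`,
#'   `>50`; must sum to 1.
#' @param share_bmi25 Proportion with BMI >= 25.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 1255,
                          share_female = 0.6397,
                          age_shares = c(0.2886, 0.4244, 0.2870),
                          share_bmi25 = 0.5288) {
  if (!is.numeric(n_users) || n_users < 1)
    stop("`n_users` must be >= 1", call. = FALSE)
  shares <- c(share_female, age_shares, share_bmi25)
  if (any(shares < 0 | shares > 1))
    stop("trait shares must lie in [0, 1]", call. = FALSE)
  if (abs(sum(age_shares) - 1) > 1e-8)
    stop("`age_shares` must sum to 1", call. = FALSE)
  structure(list(n_users = as.integer(n_users),
                 share_female = share_female,
                 age_shares = age_shares,
                 share_bmi25 = share_bmi25),
            class = "cohort_config")
}

#' Moderator / control specification for the excursion-effect model
#'
#' Defines which covariate columns form the moderator vector `f` (the
#' effect model, always containing an intercept unless slot cell-means
#' coding is requested) and which form the control vector `g` (always
#' containing an intercept).
#'
#' @param moderators Character vector of moderator column names; the
#'   intercept is implicit.  Ignored when `slot_cells = TRUE`.
#' @param controls Character vector of control column names; the
#'   intercept is implicit.
#' @param slot_cells If `TRUE`, `f` is coded as one indicator per
#'   decision slot present in the data (cell-means coding, no separate
#'   intercept; the indicators span it).
#' @param slot_by_daytype If `TRUE` (implies `slot_cells`), the slot
#'   cells are crossed with weekday/weekend, one indicator per observed
#'   slot-by-daytype cell.
#' @param p_tilde Reference randomization probability used for centering
#'   and weighting, or `NULL` (default) to use each row's recorded
#'   randomization probability, which makes every weight 1.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(moderators = character(0),
                       controls = c("week_in_study", "days_since_chart",
                                    "pushed_indicator", "push_success_ratio",
                                    "has_charted_10"),
                       slot_cells = FALSE,
                       slot_by_daytype = FALSE,
                       p_tilde = NULL) {
  if (slot_by_daytype) slot_cells <- TRUE
  if (!is.null(p_tilde) && (p_tilde <= 0 || p_tilde >= 1))
    stop("`p_tilde` must lie strictly in (0, 1)", call. = FALSE)
  structure(list(moderators = moderators, controls = controls,
                 slot_cells = slot_cells, slot_by_daytype = slot_by_daytype,
                 p_tilde = p_tilde),
            class = "model_spec")
}
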