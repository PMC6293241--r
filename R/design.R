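#' Decision slots open on a given study day
#'
#' All six daily slots are open on weekdays.  On Saturdays and Sundays
#' (when `weekend_morning_blocked` is set) every slot before noon is
#' closed; with the default schedule that removes only the 8:30 am slot.
#'
#' @param config A [trial_config()].
#' @param day_index Study day, 1-based.
#' @return Integer vector of open slot indices (subset of
#'   `seq_along(config$slot_times)`).
#' @export
slot_schedule <- function(config, day_index) {
  stopifnot(inherits(config, "trial_config"))
  if (length(day_index) != 1L || day_index < 1 || day_index > config$n_days)
    stop("`day_index` must lie in 1..", config$n_days, call. = FALSE)
  slots <- seq_along(config$slot_times)
  if (config$weekend_morning_blocked && is_weekend_day(config, day_index))
    slots <- slots[config$slot_minutes >= 12 * 60]
  slots
}

#' User state at the start of a day
#'
#' Running counters the availability rules consult.  `NA` encodes
#' "never": a user who has never charted counts days of inactivity from
#' enrollment; a user with no previous notification decision is eligible
#' for a first decision immediately.
#'
#' @param days_since_last_chart Days since the user last charted, or
#'   `NA` if never.
#' @param days_since_last_decision Days since the last notification
#'   decision, or `NA` if never.
#' @param considered_today Has a decision already been considered today?
#' @param notifications_enabled Are push notifications enabled?
#' @return A list of class `user_day_state`.
#' @export
user_day_state <- function(days_since_last_chart = NA,
                           days_since_last_decision = NA,
                           considered_today = FALSE,
                           notifications_enabled = TRUE) {
  structure(list(days_since_last_chart = days_since_last_chart,
                 days_since_last_decision = days_since_last_decision,
                 considered_today = considered_today,
                 notifications_enabled = notifications_enabled),
            class = "user_day_state")
}

#' Availability of a user at one decision slot
#'
#' A user is available at a slot iff notifications are enabled, the slot
#' is open that day, no decision has been considered yet today, and the
#' days since the last notification decision reach the wait demanded by
#' the current inactivity bucket (users with no previous decision are
#' always past the wait).
#'
#' @param state A [user_day_state()].
#' @param day_index,slot_index Day and slot being assessed.
#' @param config A [trial_config()].
#' @return `1L` (available) or `0L`.
#' @export
assess_availability <- function(state, day_index, slot_index, config) {
  stopifnot(inherits(state, "user_day_state"), inherits(config, "trial_config"))
  if (!state$notifications_enabled) return(0L)
  if (state$considered_today) return(0L)
  if (!slot_index %in% slot_schedule(config, day_index)) return(0L)
  if (!is.na(state$days_since_last_decision)) {
    inact <- if (is.na(state$days_since_last_chart)) day_index - 1L
             else state$days_since_last_chart
    if (state$days_since_last_decision < wait_days(config$rules, inact))
      return(0L)
  }
  1L
}

#' Select the considered slot among a day's open available slots
#'
#' Exactly one slot per eligible day is considered for randomization,
#' drawn uniformly among the day's open available slots (equivalently,
#' realized sequentially with probability 1/(remaining open slots) at
#' each slot).
#'
#' @param open_available_slots Integer vector of this day's open,
#'   still-available slot indices.
#' @return One slot index, or `NA_integer_` if the list is empty.
#' @export
select_considered_slot <- function(open_available_slots) {
  k <- length(open_available_slots)
  if (k == 0L) return(NA_integer_)
  open_available_slots[sample.int(k, 1L)]
}

#' Bernoulli treatment randomization at a considered decision point
#'
#' @param prob Randomization probability, strictly in (0, 1).
#' @param n Number of independent draws (default 1).
#' @return Integer vector of 0/1 treatment indicators.
#' @export
randomize_treatment <- function(prob, n = 1L) {
  if (!is.numeric(prob) || any(prob <= 0) || any(prob >= 1))
    stop("`prob` must lie strictly in (0, 1)", call. = FALSE)
  stats::rbinom(n, 1L, prob)
}

#' Run the micro-randomized trial design engine
#'
#' Walks the cohort through the decision-point grid day by day:
#' classifies availability from the inactivity rules, draws the single
#' considered slot per eligible user-day, randomizes treatment, asks the
#' outcome oracle for the day's chart event, and advances every user's
#' state.  Emits one row per user x day x slot (534 rows per user under
#' the default 89-day, 6-slot design).
#'
#' Chart events are simulated at day resolution (at most one per day, at
#' the end of the day), so the binary chart-within-24h outcome of every
#' decision slot on day `d` equals the day-`d` chart indicator, and a
#' chart on day `d` resets the inactivity clock from day `d + 1` on.
#'
#' @param n_users Number of users to simulate.
#' @param config A [trial_config()].
#' @param outcome_oracle Function `(day_state, treatment)` returning an
#'   integer 0/1 vector of chart events for the day; `day_state` is a
#'   data frame with one row per user carrying `user_id`, `day`,
#'   `is_weekend` and the derived history covariates, and `treatment`
#'   the day's push indicator (0 when no decision was considered).
#' @param disable_day Optional integer vector (length `n_users`): study
#'   day on which a user disables notifications (unavailable from that
#'   day on).  Default `Inf` for everyone, i.e. the feature is off.
#' @return A `data.frame` of decision records with columns `user_id`,
#'   `day`, `slot`, `available`, `considered`, `prob`, `sel_prob`,
#'   `push`, `outcome_24h` and the six derived covariate columns, sorted
#'   by user, day, slot.
#' @export
run_design <- function(n_users, config = trial_config(),
                       outcome_oracle, disable_day = NULL) {
  stopifnot(inherits(config, "trial_config"))
  n_users <- as.integer(n_users)
  if (n_users < 1) stop("`n_users` must be >= 1", call. = FALSE)
  if (is.null(disable_day)) disable_day <- rep(Inf, n_users)
  stopifnot(length(disable_day) == n_users)

  n_slots <- length(config$slot_times)
  n_days <- config$n_days
  n_rows <- n_users * n_days * n_slots

  out <- list(
    user_id = integer(n_rows), day = integer(n_rows), slot = integer(n_rows),
    available = integer(n_rows), considered = integer(n_rows),
    prob = rep(NA_real_, n_rows), sel_prob = rep(NA_real_, n_rows),
    push = integer(n_rows), outcome_24h = integer(n_rows),
    week_in_study = integer(n_rows), which_day = integer(n_rows),
    days_since_chart = numeric(n_rows), pushed_indicator = integer(n_rows),
    push_success_ratio = numeric(n_rows), has_charted_10 = integer(n_rows))

  # per-user running state
  last_chart <- rep(NA_integer_, n_users)
  last_dec   <- rep(NA_integer_, n_users)
  n_charts   <- integer(n_users)
  n_pushes   <- integer(n_users)
  n_success  <- integer(n_users)
  uid <- seq_len(n_users)
  p <- config$randomization_prob

  for (d in seq_len(n_days)) {
    open <- slot_schedule(config, d)
    K <- length(open)
    enabled <- d < disable_day

    inact <- ifelse(is.na(last_chart), d - 1L, d - last_chart)
    wait <- wait_days(config$rules, inact)
    eligible <- enabled & (is.na(last_dec) | (d - last_dec) >= wait)

    # position (1..K) of the considered slot among open slots; NA if none
    pos <- rep(NA_integer_, n_users)
    n_elig <- sum(eligible)
    if (n_elig > 0L)
      pos[eligible] <- sample.int(K, n_elig, replace = TRUE)
    push_day <- integer(n_users)
    if (n_elig > 0L)
      push_day[eligible] <- stats::rbinom(n_elig, 1L, p)

    day_state <- data.frame(
      user_id = uid, day = d,
      is_weekend = is_weekend_day(config, d),
      considered = as.integer(eligible),
      slot = ifelse(is.na(pos), NA_integer_, open[pmax(pos, 1L)]),
      week_in_study = (d - 1L) %/% 7L,
      which_day = as.integer(!is_weekend_day(config, d)),
      days_since_chart = pmin(inact, 30),
      days_inactive = inact,
      pushed_indicator = as.integer(n_pushes > 0L),
      push_success_ratio = ifelse(n_pushes > 0L, n_success / n_pushes, 0),
      has_charted_10 = as.integer(n_charts >= 10L))

    chart <- tryCatch(
      as.integer(outcome_oracle(day_state, push_day)),
      error = function(e) stop("outcome oracle failed on day ", d, ": ",
                               conditionMessage(e), call. = FALSE))
    if (length(chart) != n_users || anyNA(chart) || any(!chart %in% 0:1))
      stop("outcome oracle must return one 0/1 value per user (day ", d, ")",
           call. = FALSE)

    base <- (d - 1L) * n_users * n_slots
    for (s in seq_len(n_slots)) {
      idx <- base + (s - 1L) * n_users + uid
      kpos <- match(s, open)  # position of slot s among open slots, NA if closed
      avail <- eligible & !is.na(kpos) & !is.na(pos) & kpos <= pos
      cons <- avail & kpos == pos
      out$user_id[idx] <- uid
      out$day[idx] <- d
      out$slot[idx] <- s
      out$available[idx] <- as.integer(avail)
      out$considered[idx] <- as.integer(cons)
      out$prob[idx] <- ifelse(cons, p, NA_real_)
      out$sel_prob[idx] <- ifelse(avail, 1 / (K - (if (is.na(kpos)) 0L else kpos) + 1L),
                                  NA_real_)
      out$push[idx] <- as.integer(cons & push_day == 1L)
      out$outcome_24h[idx] <- chart
      out$week_in_study[idx] <- day_state$week_in_study
      out$which_day[idx] <- day_state$which_day
      out$days_since_chart[idx] <- day_state$days_since_chart
      out$pushed_indicator[idx] <- day_state$pushed_indicator
      out$push_success_ratio[idx] <- day_state$push_success_ratio
      out$has_charted_10[idx] <- day_state$has_charted_10
    }

    # advance state (decision first, then the chart event of the evening)
    last_dec[eligible] <- d
    n_pushes <- n_pushes + push_day
    n_success <- n_success + as.integer(push_day == 1L & chart == 1L)
    last_chart[chart == 1L] <- d
    n_charts <- n_charts + chart
  }

  df <- as.data.frame(out)
  df <- df[order(df$user_id, df$day, df$slot), , drop = FALSE]
  rownames(df) <- NULL
  df
}
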