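#' Sample a synthetic user cohort
#'
#' Draws baseline traits (sex, age bucket, BMI class) from the
#' configured population mix and a per-user log-scale intercept from
#' Normal(0, `user_sd`^2).  Traits are descriptive dressing only; the
#' outcome model uses just the intercept.
#'
#' @param cohort A [cohort_config()].
#' @param user_sd Standard deviation of the per-user intercept.
#' @return A `data.frame` with one row per user: `user_id`, `female`,
#'   `age_bucket` (`"<30"`, `"30-50"`, `">50"`), `bmi_ge_25`,
#'   `user_intercept`.
#' @export
sample_cohort <- function(cohort = cohort_config(), user_sd = 0.3) {
  stopifnot(inherits(cohort, "cohort_config"), user_sd >= 0)
  n <- cohort$n_users
  data.frame(
    user_id = seq_len(n),
    female = stats::rbinom(n, 1L, cohort$share_female),
    age_bucket = sample(c("<30", "30-50", ">50"), n, replace = TRUE,
                        prob = cohort$age_shares),
    bmi_ge_25 = stats::rbinom(n, 1L, cohort$share_bmi25),
    user_intercept = if (user_sd > 0) stats::rnorm(n, 0, user_sd) else numeric(n),
    stringsAsFactors = FALSE)
}

#' Daily engagement probability under the log-linear outcome model
#'
#' Computes `min(prob_cap, exp(g' alpha + b + A * f' beta))`, the
#' probability of charting within the outcome window.  The cap keeps the
#' log-linear mean a probability; defaults are chosen so it rarely binds,
#' preserving the risk-ratio contrast `exp(f' beta)`.
#'
#' @param g Numeric control covariate vector or matrix (rows = cases)
#'   conforming to `params$alpha` (including the leading intercept 1).
#' @param f Numeric moderator vector or matrix conforming to
#'   `params$beta`.
#' @param treatment 0/1 push indicator (scalar or per-row).
#' @param user_intercept Per-user log-scale intercept (scalar or per-row).
#' @param params An [outcome_params()] object.
#' @return Probability vector, strictly positive, capped at
#'   `params$prob_cap`.
#' @export
engagement_probability <- function(g, f, treatment, user_intercept, params) {
  stopifnot(inherits(params, "outcome_params"))
  g <- rbind_or_matrix(g)
  f <- rbind_or_matrix(f)
  if (ncol(g) != length(params$alpha))
    stop("`g` has ", ncol(g), " columns but `alpha` has length ",
         length(params$alpha), call. = FALSE)
  if (ncol(f) != length(params$beta))
    stop("`f` has ", ncol(f), " columns but `beta` has length ",
         length(params$beta), call. = FALSE)
  eta <- drop(g %*% params$alpha) + user_intercept +
    treatment * drop(f %*% params$beta)
  pmin(params$prob_cap, exp(eta))
}

rbind_or_matrix <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

# moderator matrix of the data-generating process, built from day-level
# state; names of the form "slot_k" map to indicators of the considered
# slot, everything else must be a day_state column
truth_moderator_matrix <- function(day_state, moderators) {
  n <- nrow(day_state)
  cols <- lapply(moderators, function(nm) {
    sl <- regmatches(nm, regexec("^slot_([0-9]+)$", nm))[[1]]
    if (length(sl) == 3L) {
      s <- as.integer(sl[3])
      ifelse(!is.na(day_state$slot) & day_state$slot == s, 1, 0)
    } else {
      if (is.null(day_state[[nm]]))
        stop("unknown moderator `", nm, "` in the data-generating model",
             call. = FALSE)
      as.numeric(day_state[[nm]])
    }
  })
  do.call(cbind, c(list(intercept = rep(1, n)), cols))
}

#' Simulate a complete micro-randomized trial dataset
#'
#' Composes the design engine with the log-linear outcome model: samples
#' a cohort, then walks it through the decision-point grid with daily
#' chart events drawn Bernoulli(engagement_probability).  Chart events
#' feed back into next-day availability and into the derived history
#' covariates.
#'
#' @param trial A [trial_config()].
#' @param cohort A [cohort_config()].
#' @param params An [outcome_params()] with the true coefficients.
#' @param seed Optional integer seed for full reproducibility.
#' @param disable_day Optional per-user notification switch-off day; see
#'   [run_design()].
#' @return A decision-record `data.frame` (see [run_design()]) with the
#'   sampled cohort attached as `attr(, "cohort")`.
#' @examples
#' d <- simulate_mrt(trial_config(n_days = 14), cohort_config(n_users = 20),
#'                   seed = 1)
#' nrow(d)  # 20 users x 14 days x 6 slots
#' @export
simulate_mrt <- function(trial = trial_config(), cohort = cohort_config(),
                         params = outcome_params(), seed = NULL,
                         disable_day = NULL) {
  stopifnot(inherits(params, "outcome_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  users <- sample_cohort(cohort, user_sd = params$user_sd)
  b <- users$user_intercept
  alpha_terms <- names(params$alpha)[-1]

  oracle <- function(day_state, treatment) {
    g <- do.call(cbind, c(list(intercept = rep(1, nrow(day_state))),
                          lapply(alpha_terms, function(nm) {
                            v <- day_state[[nm]]
                            if (is.null(v))
                              stop("control term `", nm,
                                   "` is not a day-state column", call. = FALSE)
                            as.numeric(v)
                          })))
    f <- truth_moderator_matrix(day_state, params$moderators)
    eta_hidden <- params$hidden_weekend_uplift * as.numeric(day_state$is_weekend)
    pr <- pmin(params$prob_cap,
               exp(drop(g %*% params$alpha) + b + eta_hidden +
                     treatment * drop(f %*% params$beta)))
    stats::rbinom(nrow(day_state), 1L, pr)
  }

  rec <- run_design(cohort$n_users, trial, oracle, disable_day = disable_day)
  attr(rec, "cohort") <- users
  rec
}
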