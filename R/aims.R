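ctrl5 <- c("week_in_study", "days_since_chart", "pushed_indicator",
           "push_success_ratio", "has_charted_10")

#' Preplanned analysis specifications
#'
#' Returns the moderator/control specification and Wald null of one of
#' the four preplanned analyses: the marginal (primary) effect, effect
#' moderation by week in study (secondary 1), by weekday versus weekend
#' (secondary 2, which also adds `which_day` to the controls), and the
#' exploratory time-of-day curves (slot cell means, 90% pointwise
#' intervals, no hypothesis tests).
#'
#' @param name One of `"primary"`, `"secondary1"`, `"secondary2"`,
#'   `"exploratory"`.
#' @return A list of class `aim_spec` with elements `name`, `spec` (a
#'   [model_spec()]), `test_terms` (`NULL` for exploratory) and
#'   `ci_level`.
#' @export
aim_spec <- function(name = c("primary", "secondary1", "secondary2",
                              "exploratory")) {
  name <- match.arg(name)
  out <- switch(name,
    primary = list(spec = model_spec(controls = ctrl5),
                   test_terms = "intercept", ci_level = 0.95),
    secondary1 = list(spec = model_spec(moderators = "week_in_study",
                                        controls = ctrl5),
                      test_terms = "week_in_study", ci_level = 0.95),
    secondary2 = list(spec = model_spec(moderators = "which_day",
                                        controls = c(ctrl5, "which_day")),
                      test_terms = "which_day", ci_level = 0.95),
    exploratory = list(spec = model_spec(controls = ctrl5, slot_cells = TRUE),
                       test_terms = NULL, ci_level = 0.90))
  structure(c(list(name = name), out), class = "aim_spec")
}

#' Primary analysis: marginal excursion effect of the push
#'
#' Fits the intercept-only effect model with the five history control
#' covariates, reports the marginal risk ratio with a 95% CI, and the
#' 5%-level Wald test of no effect.
#'
#' @param data Decision-record `data.frame` with derived covariates.
#' @param ... Passed to [fit_emee()] (e.g. `risk_set`).
#' @return A list of class `aim_result`: `fit`, coefficient `table`
#'   (one causal row, six control rows), the marginal `effect` (an
#'   [effect_estimate()] row), and the `wald` test.
#' @export
run_primary_aim <- function(data, ...) {
  aim <- aim_spec("primary")
  fit <- fit_emee(data, aim$spec, ...)
  structure(list(aim = "primary", fit = fit,
                 table = summary(fit, level = aim$ci_level),
                 effect = effect_estimate(fit, 1, level = aim$ci_level),
                 wald = wald_test(fit, aim$test_terms)),
            class = "aim_result")
}

#' Secondary analysis 1: effect moderation by week in study
#'
#' Fits the effect model `f = (1, week_in_study)` and reports, besides
#' the fit and the Wald test of the interaction, the per-week effect
#' curve (weeks 0 up to the last week present, 13 points under the
#' default 89-day design) on the log risk-ratio and risk-ratio scales.
#'
#' @inheritParams run_primary_aim
#' @return An `aim_result` with an extra `curve` data frame (`week`,
#'   `log_rr`, `se`, `rr`, `ci_low`, `ci_high`).
#' @export
run_secondary_aim1 <- function(data, ...) {
  aim <- aim_spec("secondary1")
  weeks <- sort(unique(data$week_in_study[data$considered == 1L]))
  if (length(weeks) < 2L)
    stop("week-in-study moderation needs at least 2 distinct weeks",
         call. = FALSE)
  fit <- fit_emee(data, aim$spec, ...)
  curve <- cbind(week = weeks,
                 effect_estimate(fit, cbind(1, weeks), level = aim$ci_level))
  structure(list(aim = "secondary1", fit = fit,
                 table = summary(fit, level = aim$ci_level),
                 curve = curve,
                 wald = wald_test(fit, aim$test_terms)),
            class = "aim_result")
}

#' Secondary analysis 2: weekday versus weekend effects
#'
#' Fits `f = (1, which_day)` with `which_day` (1 = Monday-Friday)
#' additionally adjusted for in the control model, and reports the
#' weekend effect `exp(beta_0)`, the weekday effect
#' `exp(beta_0 + beta_1)`, and the Wald test of the difference.
#'
#' @inheritParams run_primary_aim
#' @return An `aim_result` with an `effects` data frame holding the
#'   `weekend` and `weekday` risk-ratio estimates.
#' @export
run_secondary_aim2 <- function(data, ...) {
  aim <- aim_spec("secondary2")
  days <- unique(data$which_day[data$considered == 1L])
  if (length(days) < 2L)
    stop("weekday/weekend moderation needs both day types present",
         call. = FALSE)
  fit <- fit_emee(data, aim$spec, ...)
  eff <- cbind(day_type = c("weekend", "weekday"),
               effect_estimate(fit, rbind(c(1, 0), c(1, 1)),
                               level = aim$ci_level))
  structure(list(aim = "secondary2", fit = fit,
                 table = summary(fit, level = aim$ci_level),
                 effects = eff,
                 wald = wald_test(fit, aim$test_terms)),
            class = "aim_result")
}

#' Exploratory analysis: effect by time of day
#'
#' Part 1 codes the effect model as one indicator per decision slot
#' (cell means, jointly spanning the intercept); part 2 crosses the
#' slot cells with weekday/weekend.  Pointwise 90% confidence intervals
#' are reported around each cell estimate; by design no p-values are
#' produced.  Under the default schedule the weekend curve has no
#' 8:30 am point because that slot is never open on weekends.
#'
#' @inheritParams run_primary_aim
#' @param level Pointwise confidence level (default 0.90).
#' @return A list of class `exploratory_result` with `part1` (columns
#'   `slot`, `log_rr`, `se`, `rr`, `ci_low`, `ci_high`), `part2` (adds
#'   `day_type`), and the two fits.
#' @export
run_exploratory <- function(data, level = 0.90, ...) {
  slots <- sort(unique(data$slot[data$considered == 1L]))
  if (length(slots) < 2L)
    stop("time-of-day analysis needs at least 2 distinct slots", call. = FALSE)
  fit1 <- fit_emee(data, model_spec(controls = ctrl5, slot_cells = TRUE), ...)
  e1 <- cbind(slot = as.integer(sub("^slot_", "", names(fit1$beta))),
              effect_estimate(fit1, diag(length(fit1$beta)), level = level))
  fit2 <- fit_emee(data, model_spec(controls = c(ctrl5, "which_day"),
                                    slot_by_daytype = TRUE), ...)
  nm <- names(fit2$beta)
  e2 <- cbind(day_type = sub("_slot_.*$", "", nm),
              slot = as.integer(sub("^.*_slot_", "", nm)),
              effect_estimate(fit2, diag(length(fit2$beta)), level = level))
  structure(list(part1 = e1, part2 = e2, fit_part1 = fit1, fit_part2 = fit2),
            class = "exploratory_result")
}

#' Plot an excursion-effect curve
#'
#' Renders a per-week or per-slot effect curve on the log risk-ratio
#' scale (left panel) and risk-ratio scale (right panel) with its
#' pointwise confidence band.
#'
#' @param curve A curve data frame from [run_secondary_aim1()] or
#'   [run_exploratory()].
#' @param x_var Name of the x-axis column (e.g. `"week"` or `"slot"`).
#' @return A `ggplot` object.
#' @export
plot_effect_curve <- function(curve, x_var) {
  stopifnot(x_var %in% names(curve))
  long <- rbind(
    data.frame(x = curve[[x_var]], scale = "log risk ratio",
               est = curve$log_rr,
               lo = log(curve$ci_low), hi = log(curve$ci_high),
               ref = 0),
    data.frame(x = curve[[x_var]], scale = "risk ratio",
               est = curve$rr, lo = curve$ci_low, hi = curve$ci_high,
               ref = 1))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = est)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = ref),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~scale, scales = "free_y") +
    ggplot2::labs(x = x_var, y = "effect of push vs no push") +
    ggplot2::theme_bw()
}

#' Simulation scenario for the recovery experiments
#'
#' Bundles the study conditions of one simulation experiment: cohort
#' size, study length, true outcome-model parameters and the analysis
#' to run.
#'
#' @param n_users,n_days Cohort size and study length.
#' @param params True [outcome_params()] of the data-generating process.
#' @param aim Which preplanned analysis to run on each replicate.
#' @param term Excursion coefficient whose recovery is tracked (default
#'   `"intercept"`); its true value is looked up in `params$beta`.
#' @param risk_set Risk set passed to [fit_emee()].
#' @return A list of class `recovery_scenario`.
#' @export
recovery_scenario <- function(n_users = 500, n_days = 89,
                              params = outcome_params(),
                              aim = "primary", term = "intercept",
                              risk_set = "considered") {
  truth <- params$beta[[term]]
  if (is.null(truth)) stop("`term` must name an entry of params$beta",
                           call. = FALSE)
  structure(list(n_users = n_users, n_days = n_days, params = params,
                 aim = aim, term = term, truth = truth, risk_set = risk_set),
            class = "recovery_scenario")
}

#' Replicated simulate-fit-test experiment
#'
#' Runs `n_reps` independent replicates of simulate -> fit -> test under
#' a scenario and aggregates bias, RMSE, confidence-interval coverage of
#' the true coefficient, and the 5%-level Wald rejection rate for the
#' tracked term.  Fully reproducible from `(scenario, seed)`; replicate
#' failures are recorded and reported, not fatal.
#'
#' @param scenario A [recovery_scenario()].
#' @param n_reps Number of replicates (>= 2).
#' @param seed Integer master seed; per-replicate seeds are drawn from
#'   it.
#' @param level Confidence level used for coverage (default 0.95).
#' @return A list of class `recovery_report`: `truth`, `n_reps`,
#'   `estimates` (per-replicate coefficient, SE, coverage and rejection
#'   flags), `mean`, `sd`, `bias`, `rmse`, `coverage`,
#'   `rejection_rate`, `failures`.
#' @export
recovery_experiment <- function(scenario, n_reps, seed, level = 0.95) {
  stopifnot(inherits(scenario, "recovery_scenario"), n_reps >= 2)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)
  trial <- trial_config(n_days = scenario$n_days)
  cohort <- cohort_config(n_users = scenario$n_users)
  runner <- switch(scenario$aim,
                   primary = run_primary_aim,
                   secondary1 = run_secondary_aim1,
                   secondary2 = run_secondary_aim2,
                   stop("unsupported aim for recovery: ", scenario$aim))
  z <- stats::qnorm(1 - (1 - level) / 2)

  rows <- vector("list", n_reps)
  failures <- character(0)
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      d <- simulate_mrt(trial, cohort, scenario$params, seed = rep_seeds[i])
      a <- runner(d, risk_set = scenario$risk_set)
      est <- a$fit$beta[[scenario$term]]
      se <- sqrt(fit_vcov_term(a$fit, scenario$term))
      p <- wald_test(a$fit, scenario$term)$p_value
      data.frame(rep = i, seed = rep_seeds[i], estimate = est, se = se,
                 covered = abs(est - scenario$truth) <= z * se,
                 rejected = p < 0.05)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures <- c(failures, sprintf("rep %d: %s", i, res))
    else rows[[i]] <- res
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || nrow(est) == 0L)
    stop("every replicate failed; first failure: ", failures[1], call. = FALSE)
  structure(list(
    truth = scenario$truth, n_reps = n_reps, n_ok = nrow(est),
    estimates = est,
    mean = mean(est$estimate), sd = stats::sd(est$estimate),
    bias = mean(est$estimate) - scenario$truth,
    rmse = sqrt(mean((est$estimate - scenario$truth)^2)),
    coverage = mean(est$covered), rejection_rate = mean(est$rejected),
    failures = failures), class = "recovery_report")
}

fit_vcov_term <- function(fit, term) {
  j <- match(term, names(fit$beta))
  fit$vcov_beta[j, j]
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d/%d replicates ok\n", x$n_ok, x$n_reps))
  cat(sprintf("  truth %.4f | mean %.4f (sd %.4f) | bias %+.4f | rmse %.4f\n",
              x$truth, x$mean, x$sd, x$bias, x$rmse))
  cat(sprintf("  CI coverage %.3f | Wald rejection rate %.3f\n",
              x$coverage, x$rejection_rate))
  if (length(x$failures)) cat("  failures:\n   ",
                              paste(x$failures, collapse = "\n    "), "\n")
  invisible(x)
}
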