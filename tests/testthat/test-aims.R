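test_that("aim specifications match the preplanned analysis table", {
  ctrl <- c("week_in_study", "days_since_chart", "pushed_indicator",
            "push_success_ratio", "has_charted_10")
  a1 <- aim_spec("primary")
  expect_identical(a1$spec$moderators, character(0))
  expect_identical(a1$spec$controls, ctrl)
  expect_identical(a1$test_terms, "intercept")
  a2 <- aim_spec("secondary1")
  expect_identical(a2$spec$moderators, "week_in_study")
  expect_identical(a2$spec$controls, ctrl)
  expect_identical(a2$test_terms, "week_in_study")
  a3 <- aim_spec("secondary2")
  expect_identical(a3$spec$moderators, "which_day")
  expect_identical(a3$spec$controls, c(ctrl, "which_day"))
  expect_identical(a3$test_terms, "which_day")
  a4 <- aim_spec("exploratory")
  expect_true(a4$spec$slot_cells)
  expect_null(a4$test_terms)
  expect_equal(a4$ci_level, 0.90)
})

test_that("the primary analysis reports one causal and six control rows", {
  d <- quick_sim(n_users = 150, n_days = 89, seed = 67)
  res <- run_primary_aim(d)
  expect_s3_class(res, "aim_result")
  expect_equal(sum(res$table$block == "causal"), 1)
  expect_equal(sum(res$table$block == "control"), 6)
  expect_equal(res$effect$rr, exp(res$fit$beta[["intercept"]]))
  expect_equal(res$wald$df, 1)
})

test_that("week-in-study moderation produces a 13-point curve", {
  d <- quick_sim(n_users = 150, n_days = 89, seed = 71)
  res <- run_secondary_aim1(d)
  expect_equal(res$curve$week, 0:12)
  expect_equal(nrow(res$curve), 13)
  expect_equal(res$curve$rr, exp(res$curve$log_rr))
  short <- quick_sim(n_users = 30, n_days = 5, seed = 73)
  expect_error(run_secondary_aim1(short), "2 distinct weeks")
})

test_that("weekday and weekend effects combine the coefficients correctly", {
  d <- quick_sim(n_users = 150, n_days = 89, seed = 79)
  res <- run_secondary_aim2(d)
  b <- res$fit$beta
  eff <- res$effects
  expect_equal(eff$rr[eff$day_type == "weekend"], exp(b[["intercept"]]))
  expect_equal(eff$rr[eff$day_type == "weekday"],
               exp(b[["intercept"]] + b[["which_day"]]))
  # five weekdays only (day 1 is a Monday): no weekend rows, so the
  # moderator is degenerate
  wd_only <- quick_sim(n_users = 40, n_days = 5, seed = 83)
  expect_error(run_secondary_aim2(wd_only), "both day types")
})

test_that("published-style coefficient combinations reproduce the risk ratios", {
  # a weekday/weekend fit with coefficients (0.084, -0.059) implies
  # weekend rr = exp(0.084) and weekday rr = exp(0.025)
  stub <- structure(list(beta = c(intercept = 0.084, which_day = -0.059),
                         vcov_beta = diag(c(4e-4, 4e-4))),
                    class = "emee_fit")
  e <- effect_estimate(stub, rbind(c(1, 0), c(1, 1)))
  expect_equal(e$rr[1], 1.0876, tolerance = 1e-4)
  expect_equal(e$rr[2], 1.0253, tolerance = 1e-4)
})

test_that("exploratory curves are per-slot, p-value free, and skip the
           closed weekend morning", {
  d <- quick_sim(n_users = 250, n_days = 89, seed = 89)
  res <- run_exploratory(d)
  expect_false("p_value" %in% names(res$part1))
  expect_false("p_value" %in% names(res$part2))
  expect_equal(res$part1$slot, 1:6)
  wknd <- res$part2[res$part2$day_type == "weekend", ]
  expect_false(1 %in% wknd$slot)
  expect_equal(sort(wknd$slot), 2:6)
  wday <- res$part2[res$part2$day_type == "weekday", ]
  expect_equal(sort(wday$slot), 1:6)
  expect_equal(res$part1$level, rep(0.90, 6))
  # every reported rr is the exponential of its log estimate
  expect_equal(res$part2$rr, exp(res$part2$log_rr))
})

test_that("a planted weekday/weekend contrast is recovered", {
  pars <- outcome_params(beta = c(intercept = 0.25, which_day = -0.2),
                         moderators = "which_day", user_sd = 0.2)
  d <- simulate_mrt(trial_config(), cohort_config(n_users = 900),
                    pars, seed = 97)
  res <- run_secondary_aim2(d)
  se <- sqrt(diag(res$fit$vcov_beta))
  expect_lt(abs(res$fit$beta[["intercept"]] - 0.25), 4 * se[1])
  expect_lt(abs(res$fit$beta[["which_day"]] + 0.2), 4 * se[2])
})

test_that("recovery experiments are reproducible and well-formed", {
  sc <- recovery_scenario(n_users = 80, n_days = 28)
  r1 <- recovery_experiment(sc, n_reps = 3, seed = 101)
  r2 <- recovery_experiment(sc, n_reps = 3, seed = 101)
  expect_identical(r1$estimates, r2$estimates)
  expect_equal(r1$n_ok, 3)
  expect_true(r1$coverage >= 0 && r1$coverage <= 1)
  expect_true(r1$rejection_rate >= 0 && r1$rejection_rate <= 1)
  expect_equal(r1$rmse^2, r1$bias^2 + r1$sd^2 * (r1$n_ok - 1) / r1$n_ok,
               tolerance = 1e-10)
})

test_that("effect curves render on both scales", {
  d <- quick_sim(n_users = 150, n_days = 89, seed = 103)
  res <- run_secondary_aim1(d)
  p <- plot_effect_curve(res$curve, "week")
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".pdf")
  suppressMessages(ggplot2::ggsave(f, p, width = 7, height = 3.5))
  expect_true(file.size(f) > 0)
})
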