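test_that("weekday and weekend slot schedules follow the morning exclusion", {
  cfg <- trial_config()  # day 1 is a Monday
  expect_identical(slot_schedule(cfg, 1), 1:6)            # Monday
  expect_identical(slot_schedule(cfg, 5), 1:6)            # Friday
  expect_identical(slot_schedule(cfg, 6), 2:6)            # Saturday
  expect_identical(slot_schedule(cfg, 7), 2:6)            # Sunday
  open <- trial_config(weekend_morning_blocked = FALSE)
  expect_identical(slot_schedule(open, 6), 1:6)
  expect_error(slot_schedule(cfg, 0), "1\\.\\.89")
  expect_error(slot_schedule(cfg, 90), "1\\.\\.89")
})

test_that("wait rules map inactivity buckets to their waits", {
  rules <- availability_rules()
  cases <- rbind(c(0, 3), c(1, 3), c(1.9, 3), c(2, 2), c(5, 2), c(9, 2),
                 c(10, 6), c(12, 6), c(29, 6), c(30, 15), c(45, 15),
                 c(400, 15))
  expect_equal(wait_days(rules, cases[, 1]), cases[, 2])
  expect_error(wait_days(rules, -1), "nonnegative")
  expect_error(availability_rules(breaks = c(1, 2), wait_days = c(1, 1)),
               "start at 0")
  expect_error(availability_rules(wait_days = c(3, 0, 6, 15)), ">= 1")
})

test_that("slot availability combines schedule, one-per-day and wait rules", {
  cfg <- trial_config()
  st <- function(...) user_day_state(...)
  # wait of the 10-29 day bucket is 6: not yet reached vs exactly reached
  expect_equal(assess_availability(st(12, 5), 3, 3, cfg), 0L)
  expect_equal(assess_availability(st(12, 6), 3, 3, cfg), 1L)
  # a considered decision freezes the rest of the day
  expect_equal(assess_availability(st(1, 10, considered_today = TRUE),
                                   3, 4, cfg), 0L)
  # disabled notifications
  expect_equal(assess_availability(st(1, 10, notifications_enabled = FALSE),
                                   3, 4, cfg), 0L)
  # weekend morning slot closed
  expect_equal(assess_availability(st(12, 20), 6, 1, cfg), 0L)
  expect_equal(assess_availability(st(12, 20), 6, 2, cfg), 1L)
  # no decision ever made: always past the wait
  expect_equal(assess_availability(st(NA, NA), 1, 1, cfg), 1L)
})

test_that("considered-slot selection is uniform among open available slots", {
  expect_identical(select_considered_slot(integer(0)), NA_integer_)
  expect_identical(select_considered_slot(4L), 4L)
  set.seed(42)
  draws <- replicate(10000, select_considered_slot(2:6))
  freq <- tabulate(draws, 6)[2:6] / 10000
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(freq - 0.2) < 3 * se))
})

test_that("treatment randomization is Bernoulli at the recorded probability", {
  expect_error(randomize_treatment(0), "\\(0, 1\\)")
  expect_error(randomize_treatment(1), "\\(0, 1\\)")
  set.seed(7)
  draws <- randomize_treatment(0.5, 10000)
  expect_true(all(draws %in% 0:1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("the engine emits the full decision grid and is seed-deterministic", {
  oracle <- function(s, a) rep(0L, nrow(s))
  set.seed(11); d1 <- run_design(3, trial_config(), oracle)
  set.seed(11); d2 <- run_design(3, trial_config(), oracle)
  expect_identical(d1, d2)
  expect_equal(as.vector(table(d1$user_id)), rep(534, 3))
  expect_equal(nrow(d1), 3 * 89 * 6)
})

test_that("decision spacing follows the wait rules exactly", {
  # never charts: inactivity = days since enrollment, hand-traced schedule
  never <- run_design(1, trial_config(), function(s, a) rep(0L, nrow(s)))
  expect_equal(never$day[never$considered == 1],
               c(1, 3, 5, 7, 9, 15, 21, 27, 42, 57, 72, 87))
  # charts every day: inactivity stays 1, wait 3, decisions every 3 days
  always <- run_design(1, trial_config(), function(s, a) rep(1L, nrow(s)))
  expect_equal(always$day[always$considered == 1], seq(1, 89, by = 3))
})

test_that("generated tables satisfy the design invariants", {
  d <- quick_sim(n_users = 120, n_days = 60, seed = 3)
  expect_true(check_design_invariants(d, trial_config(n_days = 60)))
  # one considered slot at most per user-day
  per_day <- tapply(d$considered, paste(d$user_id, d$day), sum)
  expect_true(all(per_day <= 1))
  # row-wise implications
  expect_true(all(d$available[d$considered == 1] == 1))
  expect_true(all(d$considered[d$push == 1] == 1))
  # marginal randomization at 1/2 among considered points
  n_cons <- sum(d$considered)
  expect_lt(abs(mean(d$push[d$considered == 1]) - 0.5),
            3 * sqrt(0.25 / n_cons))
  # oracle failures carry day context
  expect_error(run_design(2, trial_config(n_days = 2),
                          function(s, a) stop("boom")),
               "oracle failed on day 1")
})

test_that("engine availability replays through the slot-level assessment", {
  cfg <- trial_config(n_days = 21)
  d <- simulate_mrt(cfg, cohort_config(n_users = 4), seed = 9)
  for (u in unique(d$user_id)) {
    du <- d[d$user_id == u, ]
    chart_day <- tapply(du$outcome_24h, du$day, max)
    last_chart <- NA; last_dec <- NA
    for (day in 1:21) {
      rows <- du[du$day == day, ]
      considered_yet <- FALSE
      for (s in 1:6) {
        st <- user_day_state(
          days_since_last_chart = if (is.na(last_chart)) NA else day - last_chart,
          days_since_last_decision = if (is.na(last_dec)) NA else day - last_dec,
          considered_today = considered_yet)
        expected <- assess_availability(st, day, s, cfg)
        expect_equal(rows$available[rows$slot == s], expected)
        if (rows$considered[rows$slot == s] == 1) considered_yet <- TRUE
      }
      if (any(rows$considered == 1)) last_dec <- day
      if (chart_day[[as.character(day)]] == 1) last_chart <- day
    }
  }
})
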