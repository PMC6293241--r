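test_that("Newton root matches the independent brute-force root", {
  toy <- read_records(toy_fixture_path())
  spec <- model_spec(controls = character(0))
  fit <- fit_emee(toy, spec)
  bf <- brute_force_root(toy)
  expect_lt(abs(fit$alpha[["intercept"]] - bf[["alpha"]]), 1e-6)
  expect_lt(abs(fit$beta[["intercept"]] - bf[["beta"]]), 1e-6)
  # closed-form cross-check: log of the treated/untreated mean ratio
  cons <- toy[toy$considered == 1, ]
  cf <- log(mean(cons$outcome_24h[cons$push == 1]) /
              mean(cons$outcome_24h[cons$push == 0]))
  expect_equal(unname(fit$beta), cf, tolerance = 1e-8)
  # on simulated data too, with a different seed and size
  d <- quick_sim(n_users = 60, n_days = 40, seed = 31)
  fit2 <- fit_emee(d, spec)
  bf2 <- brute_force_root(d)
  expect_lt(max(abs(c(fit2$alpha, fit2$beta) - bf2)), 1e-6)
})

test_that("the estimating function has mean zero at the generating truth", {
  pars <- outcome_params(alpha = c(intercept = log(0.3)),
                         beta = c(intercept = 0.1), user_sd = 0)
  d <- simulate_mrt(trial_config(), cohort_config(n_users = 500),
                    pars, seed = 37)
  ef <- emee_estfun(alpha = log(0.3), beta = 0.1, d,
                    model_spec(controls = character(0)))
  se <- apply(ef$per_user, 2, sd) / sqrt(nrow(ef$per_user))
  expect_true(all(abs(ef$U) < 3 * se))
  # the excursion block stays centered even under a misspecified control
  # model (hidden weekend uplift absent from g)
  dm <- simulate_mrt(trial_config(), cohort_config(n_users = 500),
                     misspecified_variant(pars, 0.4), seed = 41)
  alpha_m <- log(mean(dm$outcome_24h[dm$considered == 1 & dm$push == 0]))
  efm <- emee_estfun(alpha = alpha_m, beta = 0.1, dm,
                     model_spec(controls = character(0)))
  se_beta <- sd(efm$per_user[, 2]) / sqrt(nrow(efm$per_user))
  expect_lt(abs(efm$U[[2]]), 3 * se_beta)
})

test_that("reference-probability weights cancel when p_tilde equals p", {
  toy <- read_records(toy_fixture_path())
  f1 <- fit_emee(toy, model_spec(controls = character(0)))
  f2 <- fit_emee(toy, model_spec(controls = character(0), p_tilde = 0.5))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-10)
})

test_that("estimates are invariant to duplicating every user", {
  toy <- read_records(toy_fixture_path())
  dup <- toy
  dup$user_id <- dup$user_id + max(toy$user_id)
  both <- rbind(toy, dup)
  spec <- model_spec(controls = c("days_since_chart"))
  f1 <- fit_emee(toy, spec)
  f2 <- fit_emee(both, spec)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-8)
})

test_that("sandwich pieces agree between fit-time and recomputation", {
  d <- quick_sim(n_users = 80, n_days = 40, seed = 43)
  fit <- fit_emee(d)
  expect_equal(sandwich_variance(fit), unclass(fit$vcov),
               ignore_attr = TRUE, tolerance = 1e-12)
  # meat two ways: outer-product mean vs covariance plus mean outer product
  S <- fit$per_user_scores
  n <- nrow(S)
  M1 <- crossprod(S) / n
  mu <- colMeans(S)
  M2 <- stats::cov(S) * (n - 1) / n + tcrossprod(mu)
  expect_equal(M1, M2, tolerance = 1e-12)
  # symmetric positive semi-definite covariance
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  # with one record per user the clustering is degenerate: the per-user
  # scores are the per-row scores
  one <- d[d$considered == 1, ]
  one <- one[!duplicated(one$user_id), ]
  fit1 <- fit_emee(one, model_spec(controls = character(0)))
  expect_equal(nrow(fit1$per_user_scores), fit1$n_users)
})

test_that("Wald tests reduce to the right algebra", {
  d <- quick_sim(n_users = 100, n_days = 40, seed = 47)
  fit <- fit_emee(d, model_spec(moderators = "week_in_study"))
  # 1-df contrast equals the squared z statistic
  w <- wald_test(fit, "week_in_study")
  z2 <- (fit$beta[["week_in_study"]]^2 /
           fit$vcov_beta["week_in_study", "week_in_study"])
  expect_equal(w$statistic, z2, tolerance = 1e-10)
  expect_equal(w$df, 1)
  expect_equal(w$p_value, pchisq(z2, 1, lower.tail = FALSE))
  # contrast orthogonal to beta-hat gives statistic 0, p = 1
  L0 <- rbind(c(fit$beta[[2]], -fit$beta[[1]]))
  w0 <- wald_test(fit, L0)
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_equal(w0$p_value, 1)
  # chi-square tail at the textbook 5% critical value
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(wald_test(fit, rbind(c(1, 1), c(2, 2))), "rank")
  expect_error(wald_test(fit, "nope"), "unknown")
})

test_that("risk-ratio estimates exponentiate a log-symmetric interval", {
  d <- quick_sim(n_users = 100, n_days = 40, seed = 53)
  fit <- fit_emee(d, model_spec(moderators = "which_day"))
  for (x in list(c(1, 0), c(1, 1), c(1, 0.5))) {
    e <- effect_estimate(fit, x, level = 0.9)
    expect_equal(e$rr, exp(e$log_rr))
    expect_equal(e$ci_low * e$ci_high, exp(2 * e$log_rr), tolerance = 1e-10)
    expect_true(e$ci_low <= e$rr && e$rr <= e$ci_high)
  }
  expect_error(effect_estimate(fit, c(1, 0), level = 1), "\\(0, 1\\)")
  expect_error(effect_estimate(fit, c(1, 0, 0)), "conform")
})

test_that("rescaling a moderator divides its coefficient exactly", {
  d <- quick_sim(n_users = 100, n_days = 40, seed = 59)
  f1 <- fit_emee(d, model_spec(moderators = "week_in_study"))
  d2 <- d
  d2$week_in_study <- d2$week_in_study * 4
  f2 <- fit_emee(d2, model_spec(moderators = "week_in_study"))
  expect_equal(f2$beta[["week_in_study"]],
               f1$beta[["week_in_study"]] / 4, tolerance = 1e-7)
  expect_equal(f2$beta[["intercept"]], f1$beta[["intercept"]],
               tolerance = 1e-7)
})

test_that("degenerate inputs raise informative errors", {
  toy <- read_records(toy_fixture_path())
  one_user <- toy[toy$user_id == 1, ]
  expect_error(fit_emee(one_user, model_spec(controls = character(0))),
               "2 users")
  # separation: no charts in the treated arm
  sep <- toy
  sep$outcome_24h[sep$push == 1] <- 0L
  expect_error(fit_emee(sep, model_spec(controls = character(0))),
               "separation")
  # overflow is named, not silent
  expect_error(emee_estfun(alpha = 800, beta = 0, toy,
                           model_spec(controls = character(0))),
               "nonfinite")
  # constant moderator
  flat <- toy
  flat$which_day <- 1L
  expect_error(fit_emee(flat, model_spec(moderators = "which_day",
                                         controls = character(0))),
               "constant")
})

test_that("the available-person-time risk set gives a compatible estimate", {
  pars <- outcome_params(alpha = c(intercept = log(0.3)), user_sd = 0)
  d <- simulate_mrt(trial_config(), cohort_config(n_users = 400),
                    pars, seed = 61)
  f_cons <- fit_emee(d, model_spec(controls = character(0)),
                     risk_set = "considered")
  f_avail <- fit_emee(d, model_spec(controls = character(0)),
                      risk_set = "available")
  expect_gt(f_avail$n_rows, f_cons$n_rows)
  # both target the same excursion effect
  se <- sqrt(f_cons$vcov_beta[1, 1] + f_avail$vcov_beta[1, 1])
  expect_lt(abs(f_avail$beta[[1]] - f_cons$beta[[1]]), 4 * se)
})
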