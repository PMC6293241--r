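#' @name emee
#' @title Causal excursion effect estimation on the log risk-ratio scale
#'
#' @description
#' The estimator targets the causal excursion effect of sending versus
#' not sending a push notification at an available decision point on a
#' binary proximal outcome, modeled log-linearly in a moderator vector
#' `f`: the log risk ratio is `f' beta`.  Estimation solves the
#' weighted-and-centered estimating equation
#'
#' \deqn{U(\alpha,\beta)=\sum_{users}\sum_t I_t W_t
#'   \left[e^{-A_t f_t'\beta} Y_{t+1} - e^{g_t'\alpha}\right]
#'   \binom{g_t}{(A_t-\tilde p_t) f_t} = 0}
#'
#' with weights \eqn{W_t=(\tilde p_t/p_t)^{A_t}((1-\tilde p_t)/(1-p_t))^{1-A_t}}.
#' The exponential tilt `exp(-A f'beta)` blips the treated outcome down
#' to its untreated scale and the centering `(A - p_tilde) f` makes the
#' excursion coefficients consistent even when the nuisance (control)
#' model `exp(g' alpha)` is misspecified.  Users are the independent
#' units: standard errors come from a cluster-robust sandwich.
NULL

# assemble Y, A, F, G, p, ptilde, W and the user index for a fit
prepare_emee_data <- function(data, spec, risk_set = c("considered", "available")) {
  risk_set <- match.arg(risk_set)
  stopifnot(inherits(spec, "model_spec"))
  need <- c("user_id", "available", "considered", "push", "outcome_24h",
            "prob", spec$controls,
            if (!spec$slot_cells) spec$moderators else "slot",
            if (spec$slot_by_daytype) "which_day")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  if (risk_set == "considered") {
    d <- data[data$considered == 1L, , drop = FALSE]
    p <- d$prob
  } else {
    if (!"sel_prob" %in% names(data))
      stop("`available` risk set needs the `sel_prob` column", call. = FALSE)
    d <- data[data$available == 1L, , drop = FALSE]
    p_rand <- unique(stats::na.omit(data$prob))
    if (length(p_rand) != 1L)
      stop("`available` risk set requires a single randomization probability",
           call. = FALSE)
    p <- p_rand * d$sel_prob
  }
  if (nrow(d) == 0L) stop("no rows in the chosen risk set", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1))
    stop("randomization probabilities must lie strictly in (0, 1)",
         call. = FALSE)

  G <- cbind(intercept = rep(1, nrow(d)))
  for (v in spec$controls) G <- cbind(G, as.numeric(d[[v]]))
  colnames(G) <- c("intercept", spec$controls)

  if (spec$slot_cells) {
    if (spec$slot_by_daytype) {
      lev <- unique(d[, c("slot", "which_day")])
      lev <- lev[order(-lev$which_day, lev$slot), , drop = FALSE]
      F <- sapply(seq_len(nrow(lev)), function(j)
        as.numeric(d$slot == lev$slot[j] & d$which_day == lev$which_day[j]))
      colnames(F) <- paste0(ifelse(lev$which_day == 1, "weekday", "weekend"),
                            "_slot_", lev$slot)
    } else {
      lev <- sort(unique(d$slot))
      F <- sapply(lev, function(s) as.numeric(d$slot == s))
      colnames(F) <- paste0("slot_", lev)
    }
  } else {
    F <- cbind(intercept = rep(1, nrow(d)))
    for (v in spec$moderators) {
      x <- as.numeric(d[[v]])
      if (stats::var(x) == 0)
        stop("moderator `", v, "` is constant in the risk set", call. = FALSE)
      F <- cbind(F, x)
    }
    colnames(F) <- c("intercept", spec$moderators)
  }

  A <- as.numeric(d$push)
  Y <- as.numeric(d$outcome_24h)
  ptilde <- if (is.null(spec$p_tilde)) p else rep(spec$p_tilde, length(p))
  W <- (ptilde / p)^A * ((1 - ptilde) / (1 - p))^(1 - A)

  list(Y = Y, A = A, F = F, G = G, p = p, ptilde = ptilde, W = W,
       user = d$user_id, n_users = length(unique(d$user_id)))
}

emee_residual <- function(m, alpha, beta) {
  eta_g <- drop(m$G %*% alpha)
  eta_f <- drop(m$F %*% beta)
  ee <- exp(-m$A * eta_f)
  eg <- exp(eta_g)
  if (any(!is.finite(ee)) || any(!is.finite(eg))) {
    bad <- which(!is.finite(ee) | !is.finite(eg))[1]
    stop("nonfinite exponential in the estimating function at row ", bad,
         " (eta_g = ", signif(eta_g[bad], 4), ", eta_f = ",
         signif(eta_f[bad], 4), ")", call. = FALSE)
  }
  list(r = ee * m$Y - eg, eg = eg, ee = ee)
}

#' Evaluate the excursion-effect estimating function
#'
#' Returns the per-user-mean estimating function `U(alpha, beta)` and
#' the matrix of per-user contributions (rows sum to `n_users * U`).
#' Zero mean at the data-generating truth is the estimator's defining
#' property; the Monte-Carlo tests exercise it directly.
#'
#' @param alpha,beta Coefficient vectors conforming to the control and
#'   moderator matrices implied by `spec`.
#' @param data Decision-record `data.frame`.
#' @param spec A [model_spec()].
#' @param risk_set `"considered"` (default) restricts to considered
#'   decision points with their recorded randomization probability;
#'   `"available"` uses all available person-time with the implied
#'   per-slot treatment probability.
#' @return List with `U` (named vector, per-user mean) and `per_user`
#'   (matrix, one row per user).
#' @export
emee_estfun <- function(alpha, beta, data, spec = model_spec(),
                        risk_set = "considered") {
  m <- prepare_emee_data(data, spec, risk_set)
  if (length(alpha) != ncol(m$G) || length(beta) != ncol(m$F))
    stop("alpha/beta lengths do not match the model matrices", call. = FALSE)
  res <- emee_residual(m, alpha, beta)
  H <- cbind(m$G, (m$A - m$ptilde) * m$F)
  colnames(H) <- c(paste0("ctrl:", colnames(m$G)),
                   paste0("push:", colnames(m$F)))
  scores <- rowsum(m$W * res$r * H, m$user)
  list(U = colSums(scores) / m$n_users, per_user = scores)
}

emee_jacobian <- function(m, res) {
  H <- cbind(m$G, (m$A - m$ptilde) * m$F)
  Ja <- -crossprod(H, (m$W * res$eg) * m$G)
  Jb <- -crossprod(H, (m$W * m$A * m$Y * res$ee) * m$F)
  cbind(Ja, Jb) / m$n_users
}

#' Fit the causal excursion effect model
#'
#' Solves the weighted-and-centered log-linear estimating equation (see
#' [emee]) by Newton-Raphson with the analytic Jacobian, step-halving
#' line search, convergence when the sup-norm of the per-user-mean
#' estimating function drops below `tol`.  The fit is deterministic
#' given the data.
#'
#' @inheritParams emee_estfun
#' @param small_sample If `TRUE`, inflate the sandwich meat by
#'   `n/(n - q)` (q = number of coefficients), a Mancl-DeRouen-style
#'   small-sample degrees-of-freedom correction.  Default `FALSE`.
#' @param tol Convergence tolerance on the sup-norm of the per-user-mean
#'   estimating function (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `emee_fit`: coefficient vectors `alpha`
#'   and `beta`, the joint sandwich covariance `vcov` (of the estimates,
#'   i.e. already divided by the number of users), `vcov_beta`, per-user
#'   score matrix, bread/meat components, and convergence diagnostics.
#' @export
fit_emee <- function(data, spec = model_spec(), risk_set = "considered",
                     small_sample = FALSE, tol = 1e-8, max_iter = 100L) {
  m <- prepare_emee_data(data, spec, risk_set)
  if (m$n_users < 2L) stop("at least 2 users are required", call. = FALSE)
  if (all(m$A == 0) || all(m$A == 1))
    stop("both treatment arms must be present", call. = FALSE)
  # separation guard: each binary moderator cell needs charts in both arms
  for (j in seq_len(ncol(m$F))) {
    x <- m$F[, j]
    if (all(x %in% c(0, 1))) {
      act <- x == 1
      if (sum(m$Y[act & m$A == 1]) == 0 || sum(m$Y[act & m$A == 0]) == 0)
        stop("separation: no charts in one treatment arm for moderator `",
             colnames(m$F)[j], "`; the log risk ratio is not identified",
             call. = FALSE)
    }
  }

  pa <- ncol(m$G); pb <- ncol(m$F)
  y0 <- mean(m$Y[m$A == 0])
  alpha <- c(log(max(y0, 1e-3)), numeric(pa - 1L))
  beta <- numeric(pb)
  theta <- c(alpha, beta)

  ubar <- function(theta) {
    res <- emee_residual(m, theta[seq_len(pa)], theta[pa + seq_len(pb)])
    H <- cbind(m$G, (m$A - m$ptilde) * m$F)
    list(U = colSums(m$W * res$r * H) / m$n_users, res = res)
  }

  cur <- ubar(theta)
  unorm <- max(abs(cur$U))
  iter <- 0L
  while (unorm >= tol && iter < max_iter) {
    iter <- iter + 1L
    J <- emee_jacobian(m, cur$res)
    step <- tryCatch(solve(J, cur$U), error = function(e)
      stop("singular Jacobian in Newton step (condition number ",
           signif(kappa(J), 3), ")", call. = FALSE))
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      nxt <- tryCatch(ubar(cand), error = function(e) NULL)
      if (!is.null(nxt) && max(abs(nxt$U)) < unorm) break
      lambda <- lambda / 2
      if (lambda < 2^-20) {
        if (is.null(nxt)) stop("step-halving failed: estimating function ",
                               "not evaluable near the current iterate",
                               call. = FALSE)
        break
      }
    }
    theta <- cand
    cur <- nxt
    unorm <- max(abs(cur$U))
  }
  converged <- unorm < tol
  if (!converged)
    stop("Newton-Raphson did not converge in ", max_iter,
         " iterations (sup-norm of U = ", signif(unorm, 4), ")",
         call. = FALSE)

  alpha <- theta[seq_len(pa)]; beta <- theta[pa + seq_len(pb)]
  names(alpha) <- colnames(m$G); names(beta) <- colnames(m$F)

  H <- cbind(m$G, (m$A - m$ptilde) * m$F)
  scores <- rowsum(m$W * cur$res$r * H, m$user)
  colnames(scores) <- c(paste0("ctrl:", colnames(m$G)),
                        paste0("push:", colnames(m$F)))
  n <- m$n_users
  B <- emee_jacobian(m, cur$res)          # mean Jacobian (bread)
  M <- crossprod(scores) / n              # empirical score covariance (meat)
  q <- pa + pb
  if (small_sample) {
    if (n <= q) stop("small-sample correction needs n_users > #coefficients",
                     call. = FALSE)
    M <- M * n / (n - q)
  }
  Binv <- tryCatch(solve(B), error = function(e)
    stop("singular bread matrix (condition number ", signif(kappa(B), 3), ")",
         call. = FALSE))
  V <- Binv %*% M %*% t(Binv) / n
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(scores), colnames(scores))
  Vb <- V[pa + seq_len(pb), pa + seq_len(pb), drop = FALSE]
  dimnames(Vb) <- list(names(beta), names(beta))

  structure(list(alpha = alpha, beta = beta,
                 coefficients = c(alpha, beta),
                 vcov = V,
                 vcov_beta = Vb,
                 per_user_scores = scores, bread = B, meat = M,
                 n_users = n, n_rows = length(m$Y),
                 iterations = iter, converged = converged, u_norm = unorm,
                 spec = spec, risk_set = risk_set,
                 small_sample = small_sample),
            class = "emee_fit")
}

#' @export
print.emee_fit <- function(x, ...) {
  cat("Causal excursion effect fit (log risk-ratio scale)\n")
  cat(sprintf("  %d users, %d rows in risk set '%s'; converged in %d iterations\n",
              x$n_users, x$n_rows, x$risk_set, x$iterations))
  cat("\nExcursion coefficients (beta):\n")
  print(round(x$beta, 4))
  cat("\nControl coefficients (alpha):\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' @export
coef.emee_fit <- function(object, ...) c(object$alpha, object$beta)

#' @export
vcov.emee_fit <- function(object, ...) object$vcov

#' Coefficient table for an excursion-effect fit
#'
#' @param object An `emee_fit`.
#' @param level Confidence level for the (log-scale, normal-theory)
#'   intervals.
#' @param ... Unused.
#' @return A `data.frame` with one row per coefficient: `block`
#'   (`"causal"` for the excursion coefficients, `"control"` for the
#'   nuisance ones), `term`, `estimate`, `se`, `ci_low`, `ci_high`, and
#'   two-sided normal `p_value` for the causal block.
#' @export
summary.emee_fit <- function(object, level = 0.95, ...) {
  est <- c(object$alpha, object$beta)
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  pa <- length(object$alpha)
  block <- c(rep("control", pa), rep("causal", length(object$beta)))
  p <- ifelse(block == "causal",
              2 * stats::pnorm(-abs(est / se)), NA_real_)
  out <- data.frame(block = block,
                    term = c(names(object$alpha), names(object$beta)),
                    estimate = est, se = se,
                    ci_low = est - z * se, ci_high = est + z * se,
                    p_value = p, row.names = NULL)
  out[order(match(out$block, c("causal", "control"))), , drop = FALSE]
}

#' Sandwich covariance of an excursion-effect fit
#'
#' The covariance of the coefficient estimates is
#' `B^{-1} M B^{-T} / n`, with `B` the mean Jacobian of the estimating
#' function (bread) and `M` the empirical covariance of the per-user
#' score contributions (meat); users are the independent clusters, so
#' the standard errors absorb arbitrary within-person correlation of the
#' binary outcome over time.  Equals `fit$vcov` (computed at fit time);
#' exposed separately so tests can recompute it from the stored pieces.
#'
#' @param fit An `emee_fit`.
#' @param small_sample Apply the `n/(n-q)` meat inflation.
#' @return Covariance matrix of `c(alpha, beta)`.
#' @export
sandwich_variance <- function(fit, small_sample = fit$small_sample) {
  stopifnot(inherits(fit, "emee_fit"))
  n <- fit$n_users
  M <- crossprod(fit$per_user_scores) / n
  q <- length(fit$alpha) + length(fit$beta)
  if (small_sample) M <- M * n / (n - q)
  Binv <- solve(fit$bread)
  V <- Binv %*% M %*% t(Binv) / n
  (V + t(V)) / 2
}

#' Wald test of a linear hypothesis on the excursion coefficients
#'
#' Tests `L beta = 0` with the chi-square statistic
#' `(L b)' (L V L')^{-1} (L b)` on `rank(L)` degrees of freedom, `V`
#' being the sandwich covariance of the excursion-coefficient estimates.
#'
#' @param fit An `emee_fit`.
#' @param L Contrast matrix (rows = constraints, columns = excursion
#'   coefficients) or a character vector of coefficient names to test
#'   jointly against zero.
#' @return List of class `wald_test` with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, L) {
  stopifnot(inherits(fit, "emee_fit"))
  b <- fit$beta
  if (is.character(L)) {
    idx <- match(L, names(b))
    if (anyNA(idx))
      stop("unknown excursion coefficients: ",
           paste(L[is.na(idx)], collapse = ", "), call. = FALSE)
    L <- diag(length(b))[idx, , drop = FALSE]
  }
  L <- rbind(L)
  if (ncol(L) != length(b))
    stop("`L` must have one column per excursion coefficient", call. = FALSE)
  if (qr(L)$rank < nrow(L))
    stop("`L` is rank deficient", call. = FALSE)
  Vb <- fit$vcov_beta
  lb <- drop(L %*% b)
  stat <- drop(t(lb) %*% solve(L %*% Vb %*% t(L)) %*% lb)
  df <- nrow(L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Risk-ratio effect estimate at a moderator value
#'
#' Evaluates the excursion effect `x' beta` at a moderator vector `x`,
#' with a normal-theory confidence interval built on the log scale and
#' exponentiated, so the interval is asymmetric around the risk ratio
#' and log-symmetric around its logarithm.
#'
#' @param fit An `emee_fit`.
#' @param x Moderator vector conforming to `fit$beta` (e.g. `c(1, 0)`),
#'   or a matrix with one row per requested estimate.
#' @param level Confidence level in (0, 1); 0.95 default, 0.90 for the
#'   exploratory time-of-day curves.
#' @return A `data.frame` with columns `log_rr`, `se`, `rr`, `ci_low`,
#'   `ci_high`, `level` (one row per row of `x`).
#' @export
effect_estimate <- function(fit, x, level = 0.95) {
  stopifnot(inherits(fit, "emee_fit"))
  if (level <= 0 || level >= 1)
    stop("`level` must lie strictly in (0, 1)", call. = FALSE)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != length(fit$beta))
    stop("`x` must conform to the excursion coefficients", call. = FALSE)
  log_rr <- drop(x %*% fit$beta)
  se <- sqrt(rowSums((x %*% fit$vcov_beta) * x))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(log_rr = log_rr, se = se, rr = exp(log_rr),
             ci_low = exp(log_rr - z * se), ci_high = exp(log_rr + z * se),
             level = level)
}
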