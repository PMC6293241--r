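# Independent brute-force root of the intercept-only estimating equation:
# nested one-dimensional root finding (inner root in alpha for fixed beta,
# outer root in beta), touching none of the package's Newton machinery.
brute_force_root <- function(records, p_tilde = 0.5) {
  cons <- records[records$considered == 1L, ]
  Y <- cons$outcome_24h
  A <- cons$push
  alpha_of <- function(beta)
    stats::uniroot(function(a) mean(exp(-A * beta) * Y - exp(a)),
                   c(-20, 5), tol = 1e-12)$root
  outer_eq <- function(beta) {
    a <- alpha_of(beta)
    mean((A - p_tilde) * (exp(-A * beta) * Y - exp(a)))
  }
  beta <- stats::uniroot(outer_eq, c(-5, 5), tol = 1e-12)$root
  c(alpha = alpha_of(beta), beta = beta)
}

# small simulated dataset for unit tests
quick_sim <- function(n_users = 40, n_days = 30, seed = 1, ...) {
  simulate_mrt(trial_config(n_days = n_days),
               cohort_config(n_users = n_users),
               outcome_params(...), seed = seed)
}

toy_fixture_path <- function() {
  system.file("extdata", "toy_records.csv", package = "mrtpush")
}
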