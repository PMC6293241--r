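Package: mrtpush
Title: Micro-Randomized Trials of Push Notifications: Simulation and
    Causal Excursion Effect Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing
    micro-randomized trials (MRTs) of mobile push notifications with a
    binary proximal engagement outcome.  Includes a trial engine that
    reproduces a six-slot daily decision-point schedule with
    inactivity-based availability rules and Bernoulli treatment
    randomization; a synthetic cohort generator with a log-linear
    outcome model and per-user heterogeneity; an estimator of the
    marginal and moderated causal excursion effect on the log
    risk-ratio scale, solved by Newton-Raphson with an analytic
    Jacobian and paired with a cluster-robust sandwich variance and
    Wald tests; and a pipeline running the preplanned marginal,
    week-in-study, weekday/weekend and time-of-day moderation analyses
    together with simulation experiments for bias, type-I error and
    confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
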