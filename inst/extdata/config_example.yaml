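# Example study configuration for mrtpush.
# Every key is optional; omitted keys fall back to the package defaults
# (89 days, six daily slots, 50% randomization, the four-bucket
# inactivity wait table, weekend mornings blocked, 1255 users).

trial:
  n_days: 89
  slot_times: ["08:30", "12:30", "17:30", "18:30", "19:30", "20:30"]
  randomization_prob: 0.5
  weekend_morning_blocked: true
  start_weekday: 1          # 1 = Monday
  rules:
    breaks: [0, 2, 10, 30]  # left edges of the inactivity buckets (days)
    wait_days: [3, 2, 6, 15]

cohort:
  n_users: 1255
  share_female: 0.6397
  age_shares: [0.2886, 0.4244, 0.2870]
  share_bmi25: 0.5288

outcome:
  alpha:                    # true control coefficients (log scale)
    intercept: -1.25
    week_in_study: 0.0
    days_since_chart: -0.03
    pushed_indicator: -0.1
    push_success_ratio: 0.2
    has_charted_10: 0.2
  beta:                     # true excursion coefficients (log risk ratio)
    intercept: 0.04
  user_sd: 0.3
  prob_cap: 0.95

model:
  moderators: []            # intercept-only effect model (primary analysis)
  controls: [week_in_study, days_since_chart, pushed_indicator,
             push_success_ratio, has_charted_10]
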