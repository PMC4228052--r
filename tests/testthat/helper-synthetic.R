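# Shared synthetic objects for the suite.

gt_default <- ground_truth_utility()

agent_det <- agent_params(sensitivity = Inf)      # expected-utility maximiser
agent_low_noise <- agent_params(sensitivity = 200)
agent_default <- agent_params()                   # sensitivity 50

full_range_gamble <- gamble(c(0.1, 1.2))

task_gambles3 <- list(low = gamble(c(0.1, 0.4)),
                      medium = gamble(c(0.5, 0.8)),
                      high = gamble(c(0.9, 1.2)))

# Noiseless utility points from the ground truth via the fractile schedule.
exact_fractile_points <- function(gt = gt_default,
                                  schedule = build_fractile_schedule()) {
  run_fractile(exact_ce_oracle(gt), schedule)
}

# A fitted spline utility from noiseless points (cached per test file run).
fit_from_truth <- function(gt = gt_default) {
  fit_utility(exact_fractile_points(gt), domain = gt$domain)
}
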