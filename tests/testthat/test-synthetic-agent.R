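test_that("ground-truth utility respects its anchors and monotonicity", {
  gt <- gt_default
  expect_equal(true_utility(0.1, gt), 0)
  expect_equal(true_utility(1.2, gt), 1)
  # symmetric shape has utility 0.5 at the domain midpoint
  sym <- ground_truth_utility(shape_a = 2, shape_b = 2)
  expect_equal(true_utility(0.65, sym), 0.5)
  xs <- seq(0.1, 1.2, length.out = 100)
  expect_true(all(diff(true_utility(xs, gt)) > 0))
  expect_true(all(true_utility(xs, gt) >= 0 & true_utility(xs, gt) <= 1))
  expect_error(true_utility(1.3, gt), "domain")
  expect_error(true_utility(0.05, gt), "domain")
})

test_that("choice probabilities follow the logistic EU-difference rule", {
  g <- gamble(c(0.1, 1.2))
  ce <- certainty_equivalent(g, gt_default)
  # indifference: u(safe) = EU -> P(safe) = 0.5
  expect_equal(choice_prob_safe(ce, g, agent_default), 0.5, tolerance = 1e-9)
  # deterministic limit
  expect_equal(choice_prob_safe(ce + 0.05, g, agent_det), 1)
  expect_equal(choice_prob_safe(ce - 0.05, g, agent_det), 0)
  # lapse bounds the probabilities away from 0 and 1
  lapsy <- agent_params(sensitivity = Inf, lapse = 0.2)
  expect_equal(choice_prob_safe(ce + 0.05, g, lapsy), 0.9)
  expect_equal(choice_prob_safe(ce - 0.05, g, lapsy), 0.1)
  expect_error(agent_params(lapse = 0.6))
  expect_error(agent_params(sensitivity = -1))
})

test_that("agent is risk seeking for the low gamble", {
  # safe offer equal to the EV of the convex-region gamble is rejected
  # more often than not: CE > EV
  g <- gamble(c(0.1, 0.4))
  expect_lt(choice_prob_safe(expected_value(g), g, agent_default), 0.5)
  expect_gt(certainty_equivalent(g, gt_default), expected_value(g))
  # and risk avoiding for the high-value gamble
  gh <- gamble(c(0.9, 1.2))
  expect_gt(choice_prob_safe(expected_value(gh), gh, agent_default), 0.5)
  expect_lt(certainty_equivalent(gh, gt_default), expected_value(gh))
})

test_that("spike generator realises the programmed rate law", {
  gen <- dopamine_params(trial_noise_sd = 0)
  win <- c(gen$response_onset, gen$response_onset + gen$response_duration)
  rate_of <- function(train) window_response(train, win)$rate
  set.seed(101)

  # zero prediction error: in-window rate stays at baseline (3 SE check)
  n <- 1000
  r0 <- replicate(n, rate_of(generate_response(0.5, 0.5, gen)))
  se0 <- sqrt(gen$baseline_rate / (diff(win) * n))
  expect_lt(abs(mean(r0) - gen$baseline_rate), 3 * se0)

  # positive PE of 0.4 util at gain 20 -> elevation of 8 impulses/s
  rp <- replicate(n, rate_of(generate_response(0.9, 0.5, gen)))
  target <- gen$baseline_rate + 8
  expect_lt(abs(mean(rp) - target), 3 * sqrt(target / (diff(win) * n)))

  # asymmetric dynamic range: ~5-fold at attenuation 0.2
  rn <- replicate(n, rate_of(generate_response(0.1, 0.5, gen)))
  ratio <- (mean(rp) - gen$baseline_rate) / (gen$baseline_rate - mean(rn))
  expect_gt(ratio, 4)
  expect_lt(ratio, 6)
})

test_that("spike trains are valid point processes with floored rates", {
  gen <- dopamine_params(baseline_rate = 1, gain_positive = 20,
                         trial_noise_sd = 5)
  set.seed(7)
  for (i in 1:50) {
    tr <- generate_response(0.1, 0.9, gen)   # strongly negative PE
    expect_true(all(diff(tr$times) >= 0))
    expect_true(all(tr$times >= 0 & tr$times <= gen$trial_length))
  }
  expect_error(dopamine_params(baseline_rate = 9), "baseline")
  expect_error(dopamine_params(negative_attenuation = 0))
})

test_that("session simulation is balanced, bounded and reproducible", {
  task <- task_spec(task_gambles3, n_trials = 150)
  s1 <- simulate_session(task, seed = 42)
  s2 <- simulate_session(task, seed = 42)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$trials$cue)), rep(50L, 3),
               ignore_attr = TRUE)
  expect_true(all(s1$trials$iti_s >= 2 & s1$trials$iti_s <= 8))
  expect_true(all(s1$trials$delivered_ml %in%
                    unlist(lapply(task_gambles3, `[[`, "outcomes"))))
  s3 <- simulate_session(task, seed = 43)
  expect_false(identical(s1$trials$cue, s3$trials$cue))
  expect_error(task_spec(task_gambles3, n_trials = 100), "multiple")
})

test_that("agent never prefers a dominated option in the deterministic limit", {
  set.seed(99)
  for (i in 1:20) {
    lo <- runif(1, 0.1, 0.7)
    hi <- runif(1, lo + 0.1, 1.2)
    g <- gamble(c(lo, hi))
    # safe equal to the best outcome dominates the gamble; worst is dominated
    expect_equal(choice_prob_safe(hi, g, agent_det), 1)
    expect_equal(choice_prob_safe(lo, g, agent_det), 0)
  }
})
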