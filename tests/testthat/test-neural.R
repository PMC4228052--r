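test_that("prediction-error alignment times follow the liquid flow rate", {
  expect_equal(prediction_error_time(gamble(c(0.1, 0.4))), 0.025)
  expect_equal(prediction_error_time(gamble(c(0.5, 0.8))), 0.125)
  expect_equal(prediction_error_time(gamble(c(0.9, 1.2))), 0.225)
  # later alignment for larger-EV gambles
  ts <- vapply(task_gambles3, prediction_error_time, numeric(1))
  expect_true(all(diff(ts[order(vapply(task_gambles3, expected_value,
                                       numeric(1)))]) > 0))
  expect_error(prediction_error_time(gamble(c(0.1, 0.4, 0.6),
                                            probs = rep(1 / 3, 3))))
})

test_that("PSTHs bin at 10 ms, conserve counts and translate exactly", {
  # one spike centred in every bin: flat 100/s
  train <- seq(0.005, 0.995, by = 0.01)
  p <- bin_psth(list(train), window = c(0, 1))
  expect_equal(p$bin_width, 0.010)
  expect_true(all(p$rate == 100))
  expect_null(p$smoothed)

  # count conservation: sum(rate * width) = spike count in window
  set.seed(61)
  trains <- replicate(20, sort(runif(rpois(1, 30), 0, 1)),
                      simplify = FALSE)
  p2 <- bin_psth(trains, window = c(0, 1))
  expect_equal(sum(p2$rate) * p2$bin_width * p2$n_trials,
               sum(lengths(trains)))

  # shifting spikes and alignment together leaves the PSTH unchanged
  p3 <- bin_psth(list(train + 0.025), align_times = 0.025,
                 window = c(0, 1))
  p4 <- bin_psth(list(train), align_times = 0, window = c(0, 1))
  expect_equal(p3$rate, p4$rate)

  expect_error(bin_psth(list()), "empty")
})

test_that("PSTH mean matches the generator rate within Poisson error", {
  gen <- dopamine_params(trial_noise_sd = 0)
  set.seed(62)
  trains <- replicate(500, generate_response(0.5, 0.5, gen),
                      simplify = FALSE)
  p <- bin_psth(trains, window = c(0, 1))
  # flat baseline 5/s everywhere (zero PE): 3 SE over all bins pooled
  se <- sqrt(5 / (1 * 500))
  expect_lt(abs(mean(p$rate) - 5), 3 * se)
  # smoothing is display-only and flagged separately
  ps <- smooth_psth(p)
  expect_false(is.null(ps$smoothed))
  expect_equal(ps$rate, p$rate)      # raw rates untouched
})

test_that("window responses count spikes per unit time", {
  expect_equal(window_response(numeric(0), c(0.1, 0.4))$rate, 0)
  tr <- c(0.15, 0.2, 0.3, 0.55)
  wr <- window_response(tr, c(0.1, 0.4), baseline_window = c(0.4, 0.6))
  expect_equal(wr$rate, 3 / 0.3)
  expect_equal(wr$baseline, 1 / 0.2)
  expect_equal(wr$delta, 3 / 0.3 - 1 / 0.2)
  expect_error(window_response(tr, c(0.4, 0.4)), "zero-length")
  # zero-PE trials: mean delta vanishes
  gen <- dopamine_params(trial_noise_sd = 0)
  set.seed(63)
  deltas <- replicate(400, {
    t <- generate_response(0.3, 0.3, gen)
    window_response(t, c(0.1, 0.4), c(0.5, 1))$delta
  })
  expect_lt(abs(mean(deltas)), 3 * sqrt(2 * 5 / (0.3 * 400)))
})

test_that("correlation with marginal utility behaves at the extremes", {
  mu <- c(0.2, 0.5, 1.1, 0.8, 0.3, 0.9)
  r <- correlate_marginal_utility(3 * mu + 1, mu)
  expect_equal(r$rho, 1, tolerance = 1e-12)
  expect_error(correlate_marginal_utility(rep(1, 6), mu), "variance")
  # responses independent of mu: small correlations dominate
  set.seed(64)
  hits <- vapply(1:20, function(i) {
    x <- rnorm(1000)
    abs(correlate_marginal_utility(x, rep(c(0.3, 0.9, 0.5),
                                          length.out = 1000))$rho) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("Hedges' g is bias-corrected and its bootstrap CI has power", {
  x <- rnorm(5000)
  expect_equal(hedges_g(x, x, n_boot = 100)$g, 0)
  set.seed(65)
  g_big <- hedges_g(rnorm(4000, 1), rnorm(4000, 0), n_boot = 200)$g
  expect_equal(g_big, 1, tolerance = 0.1)
  # a solidly medium-large effect at n = 60: CI excludes 0 in most runs
  hits <- vapply(1:10, function(i) {
    set.seed(700 + i)
    h <- hedges_g(rnorm(60, 0.7), rnorm(60), n_boot = 2000)
    h$ci[1] > 0 || h$ci[2] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_error(hedges_g(rep(1, 5), rep(1, 5), n_boot = 10), "variance")
})

test_that("population normalisation is min-max and affine invariant", {
  m <- c(2, 8)
  expect_equal(normalize_population(m), c(0, 1))
  m2 <- c(1, 4, 2.5, 10)
  expect_equal(normalize_population(m2),
               normalize_population(3 * m2 - 7))
  expect_error(normalize_population(c(2, 2, 2)), "equal")
})

test_that("outcome responses form the inverted-U across the three gambles", {
  task <- task_spec(task_gambles3, n_trials = 150)
  resp <- simulate_neuron_population(12, task, seed = 66)
  agg <- tapply(resp$mean_delta, resp$cue, mean)
  expect_gt(agg[["medium"]], agg[["low"]])
  expect_gt(agg[["medium"]], agg[["high"]])
})

test_that("negative prediction-error responses carry less statistical power", {
  # at 5-fold attenuation, the marginal-disutility correlation over the
  # negative-outcome responses reaches significance less often than the
  # marginal-utility correlation over positive-outcome responses
  task <- task_spec(task_gambles3, n_trials = 150)
  mu_pos <- vapply(task_gambles3, function(g)
    interval_marginal_utility(gt_default, expected_value(g),
                              max(g$outcomes)), numeric(1))
  mu_neg <- vapply(task_gambles3, function(g)
    interval_marginal_utility(gt_default, min(g$outcomes),
                              expected_value(g)), numeric(1))
  p_pos <- p_neg <- numeric(4)
  for (i in 1:4) {
    rp <- simulate_neuron_population(10, task, sign = "positive",
                                     seed = 800 + i)
    rn <- simulate_neuron_population(10, task, sign = "negative",
                                     seed = 800 + i)
    p_pos[i] <- correlate_marginal_utility(rp$mean_delta,
                                           mu_pos[rp$cue])$p
    p_neg[i] <- correlate_marginal_utility(-rn$mean_delta,
                                           mu_neg[rn$cue])$p
  }
  expect_gt(mean(p_neg), mean(p_pos))
  expect_true(all(p_pos < 0.05))
})

test_that("unpredicted-reward responses trace the utility function", {
  cur <- unpredicted_reward_curve(seq(0.1, 1.2, length.out = 12),
                                  n_trials = 300, seed = 67)
  expect_lt(max(abs(cur$normalized_response - cur$normalized_utility)),
            0.12)
  expect_equal(range(cur$normalized_response), c(0, 1))
})
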