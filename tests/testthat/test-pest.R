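test_that("epsilon follows the doubling and halving rules after activation", {
  g <- full_range_gamble
  cfg <- pest_config(epsilon_init = 0.08)
  s <- pest_start(g, cfg, initial_offer = 0.5)
  # trials 1-3: epsilon fixed regardless of the choice pattern
  s <- pest_step(s, "gamble")
  s <- pest_step(s, "gamble")
  s <- pest_step(s, "gamble")
  expect_equal(s$epsilon, 0.08)
  # trial 4, two consecutive identical choices: doubled
  s <- pest_step(s, "gamble")
  expect_equal(s$epsilon, 0.16)
  # a switch: halved
  s <- pest_step(s, "safe")
  expect_equal(s$epsilon, 0.08)
  # offer moved by the pre-update epsilon at each trial
  # the post-doubling epsilon (0.16) drives the move after the switch
  expect_equal(s$offers, c(0.5, 0.58, 0.66, 0.74, 0.82, 0.66))
})

test_that("PEST converges when epsilon falls below the exit rule", {
  cfg <- pest_config(epsilon_init = 0.08, exit_rule = 0.02)
  s <- pest_start(full_range_gamble, cfg, initial_offer = 0.6)
  s <- pest_step(s, "gamble")
  s <- pest_step(s, "safe")
  s <- pest_step(s, "gamble")
  s <- pest_step(s, "safe")   # eps 0.04
  expect_equal(s$status, "running")
  s <- pest_step(s, "gamble") # eps 0.02, still >= exit rule
  expect_equal(s$status, "running")
  s <- pest_step(s, "safe")   # eps 0.01 < 0.02 -> converged
  expect_equal(s$status, "converged")
  expect_error(pest_step(s, "safe"), "converged")
  # CE is the mean of the final two offers presented
  n <- length(s$offers)
  expect_equal(pest_ce(s), mean(s$offers[c(n - 1, n)]))
})

test_that("pest_ce demands convergence and averages the last two offers", {
  cfg <- pest_config()
  s <- pest_start(full_range_gamble, cfg, initial_offer = 0.5)
  expect_error(pest_ce(s), "not converged")
  # direct arithmetic: offers ending 0.75, 0.77 -> 0.76
  s2 <- s
  s2$offers <- c(0.5, 0.75, 0.77)
  s2$status <- "converged"
  expect_equal(pest_ce(s2), 0.76)
  s2$offers <- c(0.5, 0.3, 0.3)
  expect_equal(pest_ce(s2), 0.3)
})

test_that("offers stay in range and an insatiable chooser exhausts", {
  res <- run_pest(full_range_gamble, function(safe, g) "gamble",
                  seed = 3)
  expect_equal(res$status, "exhausted")
  expect_true(is.na(res$ce))
  expect_equal(res$n_trials, pest_config()$max_trials)
  tr <- pest_trace(res)
  expect_true(all(tr$offer_ml >= 0.1 & tr$offer_ml <= 1.2))
  expect_true(all(tr$epsilon_ml > 0))
  # offers ratchet up to the top of the range
  expect_equal(max(tr$offer_ml), 1.2)
})

test_that("run_pest is deterministic under a fixed seed", {
  o <- agent_oracle(agent_default)
  r1 <- run_pest(full_range_gamble, o, seed = 11)
  r2 <- run_pest(full_range_gamble, o, seed = 11)
  expect_identical(r1, r2)
  r3 <- run_pest(full_range_gamble, o, seed = 12)
  expect_false(identical(r1$sequence$offers, r3$sequence$offers))
})

test_that("switch pairs bracket the indifference point of a deterministic agent", {
  ce_true <- certainty_equivalent(full_range_gamble, gt_default)
  o <- agent_oracle(agent_det)
  for (seed in 1:50) {
    res <- run_pest(full_range_gamble, o, seed = seed)
    expect_equal(res$status, "converged")
    tr <- pest_trace(res)
    sw <- which(tr$choice[-1] != tr$choice[-nrow(tr)]) + 1L
    for (t in sw) {
      lo <- min(tr$offer_ml[t - 1], tr$offer_ml[t])
      hi <- max(tr$offer_ml[t - 1], tr$offer_ml[t])
      expect_true(ce_true >= lo - 1e-9 && ce_true <= hi + 1e-9)
    }
  }
})

test_that("deterministic-agent CE error obeys the terminal-epsilon bound", {
  # at convergence the last update was a halving (a switch), so the final
  # two offers straddle the indifference point and their gap is the
  # pre-halving epsilon < 2 * exit rule; the error of their mean is
  # bounded by exit rule + final epsilon
  o <- agent_oracle(agent_det)
  ce_true <- certainty_equivalent(full_range_gamble, gt_default)
  cfg <- pest_config()
  errs <- vapply(1:300, function(seed) {
    res <- run_pest(full_range_gamble, o, seed = seed)
    eps_final <- res$sequence$epsilon
    err <- abs(res$ce - ce_true)
    expect_lte(err, cfg$exit_rule + eps_final + 1e-12)
    err
  }, numeric(1))
  expect_true(all(errs <= 0.04))
})

test_that("typical sequences finish within the expected trial range", {
  o <- agent_oracle(agent_det)
  nt <- vapply(1:300, function(seed)
    run_pest(full_range_gamble, o, seed = seed)$n_trials, numeric(1))
  expect_lte(median(nt), 20)
  expect_gte(median(nt), 5)
})
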