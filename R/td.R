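#' Configuration of the TD(lambda) learner
#'
#' Temporal-difference learning with accumulating eligibility traces over a
#' complete serial compound representation of the trial: each within-trial
#' time step has its own state, the cue activates the first state and the
#' reward arrives at a fixed later step. The learner treats response
#' magnitudes (e.g. normalised dopamine responses) as the delivered reward
#' signal and acquires a cue-value prediction.
#'
#' @param lambda eligibility-trace decay per step, in `[0, 1]`
#'   (default 0.9).
#' @param learning_rate step-size alpha in `(0, 1]` (default 0.1).
#' @param discount per-step discount gamma (default 1 within the trial).
#' @param n_steps within-trial time steps (default 10).
#' @param cue_step state index at which the cue occurs (default 1).
#' @param reward_step step at which the reward arrives (default 8; must be
#'   at most `n_steps`).
#' @param n_trials trials per learning run (default 1000).
#' @param n_reps independent repetitions of the run (default 2000).
#' @param stable_window number of final trials over which the stable
#'   prediction is averaged (default 200).
#' @return An object of class `"td_config"`.
#' @export
td_config <- function(lambda = 0.9, learning_rate = 0.1, discount = 1,
                      n_steps = 10, cue_step = 1, reward_step = 8,
                      n_trials = 1000, n_reps = 2000, stable_window = 200) {
  stopifnot(lambda >= 0, lambda <= 1, learning_rate >= 0,
            learning_rate <= 1, discount >= 0, discount <= 1,
            cue_step >= 1, reward_step > cue_step, reward_step <= n_steps,
            stable_window <= n_trials)
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 discount = discount, n_steps = n_steps,
                 cue_step = cue_step, reward_step = reward_step,
                 n_trials = n_trials, n_reps = n_reps,
                 stable_window = stable_window),
            class = "td_config")
}

#' Initialise TD learner state
#'
#' @param config a [td_config()].
#' @return A list with zero `weights` over the serial-compound states.
#' @export
td_state <- function(config) {
  stopifnot(inherits(config, "td_config"))
  list(weights = numeric(config$n_steps), config = config)
}

#' Run one TD(lambda) trial
#'
#' Standard update: at each step `delta_t = r_t + gamma V(s_{t+1}) -
#' V(s_t)`, `w <- w + alpha delta_t e_t`, with accumulating traces
#' `e <- gamma lambda e + indicator(s_t)`. Traces are reset at trial start;
#' the value beyond the final step is zero.
#'
#' @param state a [td_state()] (or the result of a previous trial).
#' @param reward scalar reward magnitude delivered at the configured
#'   reward step.
#' @return Updated state, with `deltas` (per-step prediction errors) and
#'   `cue_value` (the learned value of the cue state after the trial).
#' @export
td_trial <- function(state, reward) {
  cfg <- state$config
  w <- state$weights
  e <- numeric(cfg$n_steps)
  gl <- cfg$discount * cfg$lambda
  deltas <- numeric(cfg$n_steps)
  for (t in seq_len(cfg$n_steps)) {
    e <- e * gl
    e[t] <- e[t] + 1
    v_t <- w[t]
    v_next <- if (t < cfg$n_steps) w[t + 1] else 0
    r_t <- if (t == cfg$reward_step) reward else 0
    d <- r_t + cfg$discount * v_next - v_t
    w <- w + cfg$learning_rate * d * e
    deltas[t] <- d
  }
  state$weights <- w
  state$deltas <- deltas
  state$cue_value <- w[cfg$cue_step]
  state
}

# One full learning run over a reward sequence; returns the cue-value trace.
td_run <- function(rewards, config) {
  state <- td_state(config)
  vals <- numeric(length(rewards))
  for (i in seq_along(rewards)) {
    state <- td_trial(state, rewards[i])
    vals[i] <- state$cue_value
  }
  vals
}

# Balanced pseudorandom outcome schedule: draw without replacement from a
# pool containing each outcome equally often.
outcome_schedule <- function(pair, n_trials) {
  half <- n_trials %/% 2
  pool <- c(rep(pair[1], half), rep(pair[2], n_trials - half))
  sample(pool)
}

#' Train TD(lambda) on a two-outcome response pair
#'
#' Runs `n_reps` independent learning simulations of `n_trials` trials in
#' which the two response magnitudes are delivered in balanced pseudorandom
#' alternation (equal probability), and returns the stable cue prediction
#' of each run: the mean learned cue value over the final
#' `stable_window` trials. For any lambda the stable prediction converges
#' to the mean delivered magnitude.
#'
#' @param pair numeric length-2 vector of outcome magnitudes (e.g.
#'   normalised responses to the two gamble outcomes).
#' @param config a [td_config()].
#' @param seed integer seed.
#' @return Numeric vector of length `n_reps` of stable predictions.
#' @export
train_on_outcomes <- function(pair, config = td_config(), seed = 1L) {
  stopifnot(length(pair) == 2, is.numeric(pair))
  set.seed(seed)
  cfg <- config
  keep <- (cfg$n_trials - cfg$stable_window + 1):cfg$n_trials
  vapply(seq_len(cfg$n_reps), function(r) {
    vals <- td_run(outcome_schedule(pair, cfg$n_trials), cfg)
    mean(vals[keep])
  }, numeric(1))
}

#' Compare two distributions of learned values
#'
#' Two-sample t test on stable-prediction samples from
#' [train_on_outcomes()].
#'
#' @param dist_a,dist_b numeric vectors of stable predictions.
#' @return A list: `difference` (mean a - mean b), `statistic`, `p`, and a
#'   `flag` set to `"degenerate"` when either sample has zero variance.
#' @export
compare_learned_values <- function(dist_a, dist_b) {
  stopifnot(length(dist_a) >= 2, length(dist_b) >= 2)
  diff_means <- mean(dist_a) - mean(dist_b)
  if (stats::sd(dist_a) == 0 || stats::sd(dist_b) == 0) {
    return(list(difference = diff_means, statistic = NA_real_,
                p = NA_real_, flag = "degenerate"))
  }
  tt <- stats::t.test(dist_a, dist_b)
  list(difference = diff_means, statistic = unname(tt$statistic),
       p = tt$p.value, flag = "ok")
}
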