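#' Parameters of the synthetic dopamine spike generator
#'
#' Phasic midbrain dopamine responses are emulated as an inhomogeneous
#' Poisson process with a piecewise-constant rate: a low baseline rate
#' throughout the trial, shifted inside a single phasic response window by a
#' term proportional to the utility prediction error. Negative prediction
#' errors are scaled down relative to positive ones, reflecting the roughly
#' 5-fold smaller dynamic range below baseline of real dopamine neurons,
#' whose baseline firing sits below 8 impulses/s.
#'
#' @param baseline_rate baseline firing rate, impulses/s (must be < 8).
#' @param gain_positive response gain for positive prediction errors,
#'   impulses/s per util.
#' @param negative_attenuation multiplicative scale in `(0, 1]` applied to
#'   negative prediction errors; the default 0.2 encodes the ~5-fold
#'   asymmetry.
#' @param response_onset,response_duration phasic window start and length,
#'   s after the aligned event.
#' @param trial_noise_sd SD of a Gaussian trial-to-trial perturbation of the
#'   in-window rate, impulses/s.
#' @param trial_length length of the generated train, s.
#' @return An object of class `"dopamine_params"`.
#' @export
dopamine_params <- function(baseline_rate = 5, gain_positive = 20,
                            negative_attenuation = 0.2,
                            response_onset = 0.1, response_duration = 0.3,
                            trial_noise_sd = 2, trial_length = 1) {
  stopifnot(baseline_rate >= 0, baseline_rate < 8, gain_positive >= 0,
            negative_attenuation > 0, negative_attenuation <= 1,
            response_onset >= 0, response_duration > 0, trial_noise_sd >= 0,
            response_onset + response_duration <= trial_length)
  structure(list(baseline_rate = baseline_rate,
                 gain_positive = gain_positive,
                 negative_attenuation = negative_attenuation,
                 response_onset = response_onset,
                 response_duration = response_duration,
                 trial_noise_sd = trial_noise_sd,
                 trial_length = trial_length),
            class = "dopamine_params")
}

# Expected in-window firing rate for a given prediction error, before noise.
# Asymmetric rate law: baseline + gain * PE for PE >= 0,
# baseline + gain * attenuation * PE for PE < 0; floored at zero.
programmed_rate <- function(pe, p) {
  shift <- ifelse(pe >= 0, p$gain_positive * pe,
                  p$gain_positive * p$negative_attenuation * pe)
  pmax(0, p$baseline_rate + shift)
}

#' Generate one spike train encoding a utility prediction error
#'
#' Emits an inhomogeneous Poisson spike train over `[0, trial_length]` s:
#' baseline rate outside the phasic window, and inside it the baseline
#' shifted by the (signed, asymmetrically scaled, noise-perturbed,
#' floored-at-zero) prediction-error term.
#'
#' @param delivered_utility utility of the delivered outcome, util.
#' @param predicted_utility predicted utility at the aligned event, util.
#' @param p a [dopamine_params()].
#' @param meta optional named list of trial metadata stored on the train.
#' @return An object of class `"spike_train"`: a list with `times` (sorted
#'   spike times in s), the alignment window, and metadata.
#' @export
generate_response <- function(delivered_utility, predicted_utility, p,
                              meta = list()) {
  stopifnot(inherits(p, "dopamine_params"),
            delivered_utility >= 0, delivered_utility <= 1,
            predicted_utility >= 0, predicted_utility <= 1)
  pe <- delivered_utility - predicted_utility
  rate_in <- max(0, programmed_rate(pe, p) +
                   stats::rnorm(1, 0, p$trial_noise_sd))
  w0 <- p$response_onset
  w1 <- p$response_onset + p$response_duration
  segs <- rbind(c(0, w0, p$baseline_rate),
                c(w0, w1, rate_in),
                c(w1, p$trial_length, p$baseline_rate))
  times <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    len <- segs[i, 2] - segs[i, 1]
    if (len <= 0 || segs[i, 3] <= 0) next
    n <- stats::rpois(1, segs[i, 3] * len)
    if (n > 0) times <- c(times, stats::runif(n, segs[i, 1], segs[i, 2]))
  }
  structure(list(times = sort(times),
                 window = c(w0, w1),
                 prediction_error = pe,
                 meta = meta),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes, PE = %+.3f util\n",
              length(x$times), x$prediction_error))
  invisible(x)
}

#' Specify a recording-task session
#'
#' @param gambles named list of [gamble()] objects (the task cues).
#' @param n_trials total number of trials; must be a multiple of the number
#'   of gambles so the pool is balanced.
#' @param iti_lambda Poisson mean of the intertrial interval, s.
#' @param iti_range truncation bounds of the intertrial interval, s.
#' @return An object of class `"task_spec"`.
#' @export
task_spec <- function(gambles, n_trials = 150, iti_lambda = 5,
                      iti_range = c(2, 8)) {
  stopifnot(is.list(gambles), length(gambles) >= 1L,
            all(vapply(gambles, inherits, logical(1), "gamble")))
  if (is.null(names(gambles)))
    names(gambles) <- paste0("g", seq_along(gambles))
  if (n_trials %% length(gambles) != 0)
    stop("n_trials must be a multiple of the number of gambles")
  structure(list(gambles = gambles, n_trials = n_trials,
                 iti_lambda = iti_lambda, iti_range = iti_range),
            class = "task_spec")
}

# Truncated-Poisson intertrial intervals (integer seconds within the range).
sample_iti <- function(n, lambda, range) {
  support <- seq(ceiling(range[1]), floor(range[2]))
  w <- stats::dpois(support, lambda)
  sample(support, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate one recording session: trials plus spike trains
#'
#' Reproduces the structure of a nonchoice recording session: cues are drawn
#' without replacement from a balanced pool so each gamble appears equally
#' often; on each trial one of the gamble's outcomes is delivered and a
#' spike train is generated whose phasic response encodes the utility
#' prediction error (delivered utility minus the gamble's expected utility).
#' Intertrial intervals follow a truncated Poisson distribution
#' (lambda = 5 s, truncated to 2-8 s by default).
#'
#' @param task a [task_spec()].
#' @param agent an [agent_params()]; its utility defines delivered and
#'   predicted utilities.
#' @param gen a [dopamine_params()].
#' @param seed integer seed; the session is bit-reproducible given the seed.
#' @return A list with `trials` (data frame: trial, cue, outcome columns,
#'   delivered ml, delivered/predicted utility, prediction error, ITI) and
#'   `spikes` (list of [spike_train][generate_response] objects), plus the
#'   seed used.
#' @export
simulate_session <- function(task, agent = agent_params(),
                             gen = dopamine_params(), seed = 1L) {
  stopifnot(inherits(task, "task_spec"), inherits(agent, "agent_params"),
            inherits(gen, "dopamine_params"))
  set.seed(seed)
  ng <- length(task$gambles)
  pool <- rep(names(task$gambles), each = task$n_trials / ng)
  cue <- sample(pool)                      # draw without replacement
  eu <- vapply(task$gambles, expected_utility, numeric(1), u = agent$utility)
  trials <- vector("list", task$n_trials)
  spikes <- vector("list", task$n_trials)
  iti <- sample_iti(task$n_trials, task$iti_lambda, task$iti_range)
  for (t in seq_len(task$n_trials)) {
    g <- task$gambles[[cue[t]]]
    k <- sample.int(length(g$outcomes), 1, prob = g$probs)
    delivered <- g$outcomes[k]
    du <- eval_utility(agent$utility, delivered)
    spikes[[t]] <- generate_response(du, eu[[cue[t]]], gen,
                                     meta = list(trial = t, cue = cue[t],
                                                 delivered_ml = delivered))
    trials[[t]] <- data.frame(trial = t, cue = cue[t],
                              outcome_lo = min(g$outcomes),
                              outcome_hi = max(g$outcomes),
                              delivered_ml = delivered,
                              delivered_util = du,
                              predicted_util = eu[[cue[t]]],
                              pe_util = du - eu[[cue[t]]],
                              iti_s = iti[t])
  }
  list(trials = do.call(rbind, trials), spikes = spikes, seed = seed)
}

#' Simulate a choice session between gambles and safe rewards
#'
#' Generates the trial table used for the psychometric fit and the
#' choice-determinant regression: on each trial one gamble and one safe
#' volume are presented, the side of the safe cue is randomised, and the
#' agent chooses by the logistic EU-difference rule. Accumulated delivered
#' reward and the prior outcome (delivered minus predicted value, in ml) are
#' tracked across the session.
#'
#' @param gambles list of [gamble()] objects to sample from.
#' @param safe_volumes numeric vector of safe volumes to sample from
#'   (flat distribution, independent of the agent's history).
#' @param n_trials number of trials.
#' @param agent an [agent_params()].
#' @param seed integer seed.
#' @return Data frame with columns `trial`, `gamble_id`, `gamble_value`
#'   (EV, ml), `safe_ml`, `safe_side`, `accumulated_ml`, `prior_outcome`,
#'   `chose_safe`, `delivered_ml`.
#' @export
simulate_choice_session <- function(gambles, safe_volumes, n_trials = 500,
                                    agent = agent_params(), seed = 1L) {
  stopifnot(all(vapply(gambles, inherits, logical(1), "gamble")),
            n_trials >= 1)
  set.seed(seed)
  gid <- sample.int(length(gambles), n_trials, replace = TRUE)
  safe <- sample(safe_volumes, n_trials, replace = TRUE)
  side <- sample(c(-1, 1), n_trials, replace = TRUE)  # -1 left, +1 right
  ev <- vapply(gambles, expected_value, numeric(1))
  p_safe <- vapply(seq_len(n_trials), function(t)
    choice_prob_safe(safe[t], gambles[[gid[t]]], agent), numeric(1))
  chose_safe <- stats::runif(n_trials) < p_safe
  delivered <- numeric(n_trials)
  outcome_pe <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    if (chose_safe[t]) {
      delivered[t] <- safe[t]
    } else {
      g <- gambles[[gid[t]]]
      delivered[t] <- g$outcomes[sample.int(length(g$outcomes), 1,
                                            prob = g$probs)]
      outcome_pe[t] <- delivered[t] - ev[gid[t]]
    }
  }
  data.frame(trial = seq_len(n_trials), gamble_id = gid,
             gamble_value = ev[gid], safe_ml = safe, safe_side = side,
             accumulated_ml = c(0, cumsum(delivered)[-n_trials]),
             prior_outcome = c(0, outcome_pe[-n_trials]),
             chose_safe = chose_safe, delivered_ml = delivered)
}
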