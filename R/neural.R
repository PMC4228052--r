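#' Time of the outcome prediction error under constant liquid flow
#'
#' Juice is delivered by a solenoid valve with a fixed flow rate, so reward
#' volume maps linearly onto valve opening time. For a two-outcome gamble
#' the onset of juice itself carries no prediction error -- both outcomes
#' start identically -- but flow continuing past the time at which the
#' smaller outcome would have ended signals the larger outcome. Responses
#' are therefore aligned to `min(outcome) / flow_rate` after juice onset.
#'
#' @param g a two-outcome [gamble()].
#' @param flow_rate valve flow rate in ml per ms (default 0.004).
#' @return Alignment time in seconds after juice onset (0.1 ml -> 0.025 s).
#' @export
prediction_error_time <- function(g, flow_rate = 0.004) {
  stopifnot(inherits(g, "gamble"), length(g$outcomes) == 2)
  if (any(g$outcomes <= 0)) stop("outcomes must be positive")
  (min(g$outcomes) / flow_rate) / 1000
}

#' Default analysis windows
#'
#' Post-event windows (s) capturing the major phasic response components:
#' fixation 0.100-0.400, cue 0.100-0.550, juice 0.050-0.350, unpredicted
#' reward 0.200-0.500.
#'
#' @param event one of `"fixation"`, `"cue"`, `"juice"`, `"unpredicted"`.
#' @return Numeric `c(start, end)` in s.
#' @export
analysis_window <- function(event = c("fixation", "cue", "juice",
                                      "unpredicted")) {
  event <- match.arg(event)
  switch(event,
         fixation = c(0.100, 0.400),
         cue = c(0.100, 0.550),
         juice = c(0.050, 0.350),
         unpredicted = c(0.200, 0.500))
}

#' Peristimulus time histogram
#'
#' Mean firing rate across trials in nonoverlapping 10 ms bins, aligned to
#' a per-trial event time. An optional moving-average smoothed copy can be
#' added for display with [smooth_psth()]; statistics always use the raw
#' binned rates.
#'
#' @param trains list of [spike_train][generate_response] objects (or plain
#'   numeric vectors of spike times).
#' @param align_times per-trial alignment times, s (recycled if length 1).
#' @param window PSTH extent around the alignment time, s.
#' @param bin_width bin width in s; fixed at 0.010 by convention.
#' @return An object of class `"psth"`: `bin_edges`, `rate` (impulses/s per
#'   bin), `n_trials`, `smoothed` (`NULL` until smoothing is requested).
#' @export
bin_psth <- function(trains, align_times = 0, window = c(-0.5, 1),
                     bin_width = 0.010) {
  if (length(trains) == 0) stop("empty train set")
  times <- lapply(trains, function(tr)
    if (inherits(tr, "spike_train")) tr$times else as.numeric(tr))
  n <- length(times)
  align_times <- rep_len(align_times, n)
  edges <- seq(window[1], window[2], by = bin_width)
  counts <- matrix(0, n, length(edges) - 1)
  for (i in seq_len(n)) {
    t <- times[[i]] - align_times[i]
    t <- t[t >= window[1] & t < window[2]]
    if (length(t))
      counts[i, ] <- tabulate(findInterval(t, edges), length(edges) - 1)
  }
  structure(list(bin_edges = edges,
                 rate = colMeans(counts) / bin_width,
                 n_trials = n, bin_width = bin_width, smoothed = NULL),
            class = "psth")
}

#' Add a moving-average smoothed copy to a PSTH (display only)
#'
#' @param p a `"psth"`.
#' @param width smoothing window in s (default 0.070).
#' @return The PSTH with a `smoothed` rate vector attached.
#' @export
smooth_psth <- function(p, width = 0.070) {
  stopifnot(inherits(p, "psth"))
  k <- max(1L, round(width / p$bin_width))
  if (k %% 2 == 0) k <- k + 1L
  kern <- rep(1 / k, k)
  p$smoothed <- as.numeric(stats::filter(p$rate, kern, sides = 2))
  p
}

#' @export
plot.psth <- function(x, ...) {
  mids <- x$bin_edges[-length(x$bin_edges)] + x$bin_width / 2
  graphics::plot(mids, x$rate, type = "s", xlab = "time (s)",
                 ylab = "rate (impulses/s)", ...)
  if (!is.null(x$smoothed)) graphics::lines(mids, x$smoothed, col = 2)
  invisible(x)
}

#' Windowed firing rate and baseline of one spike train
#'
#' Spike count divided by window duration, in the response window and a
#' baseline window, plus their difference.
#'
#' @param train a [spike_train][generate_response] or numeric spike times, s.
#' @param window response window `c(start, end)`, s.
#' @param baseline_window baseline window `c(start, end)`, s.
#' @return A list: `rate`, `baseline`, `delta` (impulses/s).
#' @export
window_response <- function(train, window,
                            baseline_window = c(-0.5, 0)) {
  t <- if (inherits(train, "spike_train")) train$times else
    as.numeric(train)
  for (w in list(window, baseline_window))
    if (diff(w) <= 0) stop("zero-length window")
  rate <- sum(t >= window[1] & t < window[2]) / diff(window)
  base <- sum(t >= baseline_window[1] & t < baseline_window[2]) /
    diff(baseline_window)
  list(rate = rate, baseline = base, delta = rate - base)
}

#' Pearson correlation of responses with marginal utility
#'
#' @param responses numeric vector of response magnitudes (one per
#'   neuron-condition observation).
#' @param mu marginal utility of the matching condition for each
#'   observation.
#' @return A list: `rho`, `p`, `n`.
#' @export
correlate_marginal_utility <- function(responses, mu) {
  stopifnot(length(responses) == length(mu), length(responses) >= 3)
  if (stats::sd(responses) == 0 || stats::sd(mu) == 0)
    stop("zero variance in responses or marginal utilities")
  ct <- stats::cor.test(responses, mu, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(responses))
}

#' Hedges' g effect size with bootstrap confidence interval
#'
#' Bias-corrected standardised mean difference between two samples
#' (values around 0.2, 0.5 and 0.8 indicate small, medium and large
#' effects). The confidence interval is a bootstrap percentile interval.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level.
#' @return A list: `g`, `ci`, `n_boot`.
#' @export
hedges_g <- function(a, b, n_boot = 10000, conf = 0.95) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  gfun <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    d <- (mean(a) - mean(b)) / sqrt(sp2)
    d * (1 - 3 / (4 * (na + nb) - 9))       # small-sample bias correction
  }
  g <- gfun(a, b)
  boots <- vapply(seq_len(n_boot), function(i)
    gfun(sample(a, replace = TRUE), sample(b, replace = TRUE)), numeric(1))
  alpha <- (1 - conf) / 2
  list(g = g, ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_boot = n_boot)
}

#' Min-max normalisation of population condition means
#'
#' Maps condition means onto `[0, 1]`; invariant under affine transforms of
#' the input.
#'
#' @param means numeric vector of per-condition population means (>= 2).
#' @return Normalised vector in `[0, 1]`.
#' @export
normalize_population <- function(means) {
  stopifnot(length(means) >= 2)
  r <- range(means)
  if (diff(r) == 0) stop("all condition means are equal")
  (means - r[1]) / diff(r)
}

#' Simulate a population of synthetic dopamine neurons
#'
#' Runs one recording session per neuron (seeded deterministically from
#' `seed`) and tabulates the windowed outcome responses: for every neuron
#' and gamble, the mean response-window rate minus baseline on trials where
#' the larger (`"positive"`) or smaller (`"negative"`) outcome was
#' delivered, aligned conceptually to the prediction-error time of each
#' gamble.
#'
#' @param n_neurons number of neurons.
#' @param task a [task_spec()].
#' @param agent an [agent_params()].
#' @param gen a [dopamine_params()].
#' @param sign `"positive"` or `"negative"`: which outcome's trials to
#'   tabulate.
#' @param seed integer seed.
#' @return A data frame (one row per neuron x gamble): `neuron`, `cue`,
#'   `mean_delta` (impulses/s), `n_trials_used`, `pe_util`.
#' @export
simulate_neuron_population <- function(n_neurons, task,
                                       agent = agent_params(),
                                       gen = dopamine_params(),
                                       sign = c("positive", "negative"),
                                       seed = 1L) {
  sign <- match.arg(sign)
  win <- c(gen$response_onset, gen$response_onset + gen$response_duration)
  rows <- list()
  for (j in seq_len(n_neurons)) {
    ses <- simulate_session(task, agent, gen,
                            seed = derive_seed(seed, paste0("neuron", j)))
    tr <- ses$trials
    pick_hi <- tr$delivered_ml == tr$outcome_hi
    keep <- if (sign == "positive") pick_hi else !pick_hi
    for (cue in names(task$gambles)) {
      idx <- which(keep & tr$cue == cue)
      deltas <- vapply(idx, function(i) {
        wr <- window_response(ses$spikes[[i]], win, c(0, gen$response_onset))
        wr$rate - gen$baseline_rate
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(neuron = j, cue = cue, mean_delta = mean(deltas),
                   n_trials_used = length(idx),
                   pe_util = tr$pe_util[idx[1]])
    }
  }
  do.call(rbind, rows)
}

#' Population response curve to unpredicted rewards
#'
#' Delivers each reward magnitude outside any predictive context (the
#' moment-by-moment prediction is zero), simulates phasic responses, and
#' returns the min-max-normalised population mean response per magnitude
#' alongside the normalised utility of each magnitude. In this setting the
#' marginal utility of each reward is, by construction, the utility gained
#' over the zero prediction, so the normalised response curve should track
#' the utility function itself.
#'
#' @param magnitudes reward volumes in ml.
#' @param n_trials trials per magnitude.
#' @param agent an [agent_params()] supplying the generating utility.
#' @param gen a [dopamine_params()].
#' @param seed integer seed.
#' @return A data frame: `magnitude_ml`, `mean_delta`,
#'   `normalized_response`, `utility`, `normalized_utility`.
#' @export
unpredicted_reward_curve <- function(magnitudes, n_trials = 200,
                                     agent = agent_params(),
                                     gen = dopamine_params(), seed = 1L) {
  stopifnot(length(magnitudes) >= 2)
  set.seed(seed)
  win <- c(gen$response_onset, gen$response_onset + gen$response_duration)
  u <- vapply(magnitudes, function(m) eval_utility(agent$utility, m),
              numeric(1))
  mean_delta <- vapply(seq_along(magnitudes), function(k) {
    deltas <- vapply(seq_len(n_trials), function(i) {
      tr <- generate_response(u[k], 0, gen)
      window_response(tr, win, c(0, gen$response_onset))$rate -
        gen$baseline_rate
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  data.frame(magnitude_ml = magnitudes, mean_delta = mean_delta,
             normalized_response = normalize_population(mean_delta),
             utility = u,
             normalized_utility = normalize_population(u))
}
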