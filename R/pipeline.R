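#' Configuration of the full synthetic experiment
#'
#' Bundles every stage's parameters with one master seed. Child seeds for
#' each stage are derived deterministically via [derive_seed()], so any
#' stage can be reproduced in isolation. The default task gambles are the
#' three recording-task gambles with small, medium and large expected
#' values (0.25, 0.65 and 1.05 ml).
#'
#' @param agent an [agent_params()].
#' @param pest a [pest_config()].
#' @param fractile_depth,fractile_repeats fractile schedule depth and CE
#'   repeats per node.
#' @param task_gambles named list of [gamble()]s for the recording task.
#' @param gen a [dopamine_params()].
#' @param td a [td_config()].
#' @param n_sessions number of simulated utility-measurement sessions.
#' @param n_neurons number of simulated neurons for the outcome-response
#'   analysis.
#' @param master_seed integer master seed.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(agent = agent_params(),
                              pest = pest_config(),
                              fractile_depth = 3, fractile_repeats = 3,
                              task_gambles = list(
                                low = gamble(c(0.1, 0.4)),
                                medium = gamble(c(0.5, 0.8)),
                                high = gamble(c(0.9, 1.2))),
                              gen = dopamine_params(),
                              td = td_config(),
                              n_sessions = 14, n_neurons = 52,
                              master_seed = 1L) {
  stopifnot(inherits(agent, "agent_params"), inherits(pest, "pest_config"),
            inherits(gen, "dopamine_params"), inherits(td, "td_config"),
            fractile_depth >= 1, fractile_repeats >= 1, n_sessions >= 2,
            n_neurons >= 1)
  dom <- if (inherits(agent$utility, "ground_truth"))
    agent$utility$domain else pest$safe_range
  for (g in task_gambles) {
    if (any(g$outcomes < dom[1] - 1e-9 | g$outcomes > dom[2] + 1e-9))
      stop("task gamble outcomes outside the utility domain")
  }
  structure(list(agent = agent, pest = pest,
                 fractile_depth = fractile_depth,
                 fractile_repeats = fractile_repeats,
                 task_gambles = task_gambles, gen = gen, td = td,
                 n_sessions = n_sessions, n_neurons = n_neurons,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Measure one session's utility function from a synthetic agent
#'
#' One fractile session: every schedule node's CE is measured with PEST
#' (averaged over repeats), and the resulting points are fitted with the
#' monotone cubic spline.
#'
#' @param config an [experiment_config()].
#' @param session_seed integer seed for this session.
#' @return A list: `points` (utility points), `fit` (`"utility_fn"`).
#' @export
measure_utility_session <- function(config, session_seed = 1L) {
  set.seed(session_seed)
  sched <- build_fractile_schedule(
    domain = config$pest$safe_range, depth = config$fractile_depth)
  oracle <- pest_ce_oracle(config$agent, config$pest)
  pts <- run_fractile(oracle, sched, repeats = config$fractile_repeats)
  fit <- fit_utility(pts, domain = config$pest$safe_range,
                     seed = derive_seed(session_seed, "knots"))
  list(points = pts, fit = fit)
}

#' Run the full synthetic experiment
#'
#' Orchestrates the complete chain: utility measurement over several
#' sessions (PEST within the fractile schedule, monotone spline fits,
#' session averaging), out-of-sample validation, stochastic-dominance
#' verdicts for the task gambles, simulated dopamine outcome responses and
#' their correlation with marginal utility, the unpredicted-reward response
#' curve, and TD(lambda) training on the response magnitudes of an
#' equal-EV gamble pair. Optionally writes all stage outputs (CSV/JSON)
#' under `outdir`.
#'
#' @param config an [experiment_config()].
#' @param outdir optional output directory; created if missing.
#' @param td_reps optional override of the TD repetition count (the full
#'   2000 repetitions are slow; smaller values preserve the comparison).
#' @return A list of class `"experiment_report"` with one element per
#'   stage and a machine-readable `summary`.
#' @export
run_full <- function(config = experiment_config(), outdir = NULL,
                     td_reps = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  dom <- config$pest$safe_range

  ## 1. utility measurement across sessions
  sessions <- lapply(seq_len(config$n_sessions), function(s)
    measure_utility_session(config, derive_seed(ms, paste0("session", s))))
  fits <- lapply(sessions, `[[`, "fit")
  band <- average_sessions(fits)
  u <- fits[[1]]

  ## 2. CE versus EV risk attitude for the task gambles (first session fit)
  ce_tab <- do.call(rbind, lapply(names(config$task_gambles), function(nm) {
    g <- config$task_gambles[[nm]]
    data.frame(cue = nm, ev_ml = expected_value(g),
               ce_ml = as.numeric(certainty_equivalent(g, u)),
               eu = expected_utility(g, u))
  }))

  ## 3. out-of-sample validation
  set.seed(derive_seed(ms, "validation"))
  val_g <- default_validation_gambles(dom)
  oracle <- pest_ce_oracle(config$agent, config$pest)
  val_ce <- vapply(val_g, function(g) {
    ces <- vapply(seq_len(config$fractile_repeats),
                  function(r) oracle(g), numeric(1))
    mean(ces)
  }, numeric(1))
  validation <- validate_out_of_sample(u, val_g, val_ce)

  ## 4. dominance verdicts
  g_names <- names(config$task_gambles)
  dom_tab <- list()
  for (i in seq_along(config$task_gambles)) {
    gi <- config$task_gambles[[i]]
    safe_hi <- gamble(max(gi$outcomes))
    safe_lo <- gamble(min(gi$outcomes))
    dom_tab[[length(dom_tab) + 1L]] <- data.frame(
      cue = g_names[i],
      vs_high_safe = fosd(safe_hi, gi), vs_low_safe = fosd(gi, safe_lo))
  }
  risk_pair <- list(riskier = gamble(c(dom[1], dom[2])),
                    safer = gamble(dom[1] + diff(dom) * c(4, 7) / 11))
  mps <- is_mean_preserving_spread(risk_pair$riskier, risk_pair$safer)
  sosd <- sosd_preference(risk_pair$riskier, risk_pair$safer, u)

  ## 5. neural outcome responses and marginal-utility correlation
  task <- task_spec(config$task_gambles, n_trials = 150)
  resp <- simulate_neuron_population(config$n_neurons, task, config$agent,
                                     config$gen,
                                     seed = derive_seed(ms, "neurons"))
  # positive-PE interval: from the predicted value (EV) to the larger
  # outcome of each gamble
  mu_tab <- vapply(config$task_gambles, function(g)
    interval_marginal_utility(u, expected_value(g), max(g$outcomes)),
    numeric(1))
  mu_cor <- correlate_marginal_utility(resp$mean_delta,
                                       mu_tab[resp$cue])

  ## 6. unpredicted-reward response curve
  mags <- seq(dom[1], dom[2], length.out = 12)
  curve <- unpredicted_reward_curve(mags, n_trials = 200, config$agent,
                                    config$gen,
                                    seed = derive_seed(ms, "unpredicted"))

  ## 7. TD training on the equal-EV gamble pair's response magnitudes
  td_cfg <- config$td
  if (!is.null(td_reps)) td_cfg$n_reps <- td_reps
  resp_at <- function(ml) curve$normalized_response[
    which.min(abs(curve$magnitude_ml - ml))]
  pair_risky <- vapply(risk_pair$riskier$outcomes, resp_at, numeric(1))
  pair_safe <- vapply(risk_pair$safer$outcomes, resp_at, numeric(1))
  td_risky <- train_on_outcomes(pair_risky, td_cfg,
                                seed = derive_seed(ms, "td-risky"))
  td_safe <- train_on_outcomes(pair_safe, td_cfg,
                               seed = derive_seed(ms, "td-safe"))
  td_cmp <- compare_learned_values(td_risky, td_safe)

  summary <- list(
    master_seed = ms,
    n_sessions = config$n_sessions,
    ce_table = ce_tab,
    deming_slope = validation$fit$slope,
    residual_rho = validation$residual_cor$rho,
    mps_detected = mps,
    sosd_preferred = sosd$preferred,
    mu_response_rho = mu_cor$rho,
    mu_response_p = mu_cor$p,
    td_value_risky = mean(td_risky),
    td_value_safe = mean(td_safe),
    td_p = td_cmp$p)

  report <- structure(list(sessions = sessions, band = band,
                           ce_table = ce_tab, validation = validation,
                           dominance = do.call(rbind, dom_tab),
                           mps = mps, sosd = sosd, responses = resp,
                           mu_cor = mu_cor, unpredicted = curve,
                           td = list(risky = td_risky, safe = td_safe,
                                     comparison = td_cmp),
                           summary = summary, config = config),
                      class = "experiment_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sessions[[1]]$points,
                     file.path(outdir, "utility_points.csv"),
                     row.names = FALSE)
    write_utility_fn(u, file.path(outdir, "utility_fit.json"))
    utils::write.csv(ce_tab, file.path(outdir, "ce_table.csv"),
                     row.names = FALSE)
    utils::write.csv(resp, file.path(outdir, "response_table.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(outdir, "unpredicted_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(risky = td_risky, safe = td_safe),
                     file.path(outdir, "td_predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Synthetic experiment report (seed", x$summary$master_seed, ")\n")
  cat("  CE vs EV:\n")
  print(x$ce_table, digits = 3)
  cat(sprintf("  Deming slope (out of sample): %.3f\n",
              x$summary$deming_slope))
  cat(sprintf("  response ~ marginal utility: rho = %.3f (p = %.2g)\n",
              x$summary$mu_response_rho, x$summary$mu_response_p))
  cat(sprintf("  TD value, riskier vs safer equal-EV pair: %.3f vs %.3f (p = %.2g)\n",
              x$summary$td_value_risky, x$summary$td_value_safe,
              x$summary$td_p))
  invisible(x)
}

#' Write small deterministic fixtures for tests and examples
#'
#' Writes one PEST trace (CSV), one fractile utility point set (CSV) and 20
#' spike trains (plain text) under `dir`, all generated from `seed`.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  agent <- agent_params()
  res <- run_pest(gamble(c(0.1, 1.2)), agent_oracle(agent),
                  seed = derive_seed(seed, "fixture-pest"))
  p_trace <- file.path(dir, "pest_trace.csv")
  utils::write.csv(pest_trace(res), p_trace, row.names = FALSE)

  set.seed(derive_seed(seed, "fixture-fractile"))
  pts <- run_fractile(exact_ce_oracle(agent$utility))
  p_pts <- file.path(dir, "utility_points.csv")
  utils::write.csv(pts, p_pts, row.names = FALSE)

  set.seed(derive_seed(seed, "fixture-spikes"))
  gen <- dopamine_params()
  trains <- lapply(seq_len(20), function(i)
    generate_response(stats::runif(1), 0.5, gen))
  p_spk <- file.path(dir, "spike_trains.txt")
  write_spike_trains(trains, p_spk)
  invisible(c(p_trace, p_pts, p_spk))
}
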