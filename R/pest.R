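#' Configuration of the PEST adaptive staircase
#'
#' Parameter Estimation by Sequential Testing adjusts the safe offer of a
#' constant gamble-versus-safe choice by a step epsilon: the offer moves up
#' after a gamble choice and down after a safe choice. From the fourth trial
#' on, epsilon is doubled whenever two consecutive choices agree and halved
#' whenever they differ; the sequence terminates once epsilon falls below
#' the exit rule.
#'
#' @param epsilon_init initial step size, ml. The staircase literature only
#'   requires it to be "large"; 0.2 ml (about a fifth of the offer range)
#'   reaches any point of the range quickly under doubling while converging
#'   within the typical 15-20 trials.
#' @param exit_rule convergence threshold on epsilon, ml (default 0.020 ml,
#'   i.e. 20 microliters).
#' @param safe_range representable safe offer range, ml; offers are clamped
#'   to it without altering the epsilon bookkeeping.
#' @param max_trials safety cap; a sequence hitting it is flagged
#'   `exhausted`, never silently returned as converged.
#' @param fixed_epsilon_trials number of initial trials on which epsilon is
#'   held fixed before the doubling/halving rules activate (default 3).
#' @return An object of class `"pest_config"`.
#' @export
pest_config <- function(epsilon_init = 0.2, exit_rule = 0.020,
                        safe_range = c(0.1, 1.2), max_trials = 50,
                        fixed_epsilon_trials = 3) {
  stopifnot(exit_rule > 0, epsilon_init > exit_rule,
            length(safe_range) == 2L, safe_range[1] < safe_range[2],
            max_trials >= 2, fixed_epsilon_trials >= 1)
  structure(list(epsilon_init = epsilon_init, exit_rule = exit_rule,
                 safe_range = safe_range, max_trials = max_trials,
                 fixed_epsilon_trials = fixed_epsilon_trials),
            class = "pest_config")
}

#' Start a PEST sequence
#'
#' @param g the constant [gamble()] of the sequence.
#' @param config a [pest_config()].
#' @param initial_offer first safe offer, ml; if `NULL`, drawn uniformly
#'   from the safe range (consuming the R random stream).
#' @return An object of class `"pest_seq"` with fields `offers`, `choices`,
#'   `epsilon`, `epsilon_history` and `status`
#'   (`"running"`/`"converged"`/`"exhausted"`).
#' @export
pest_start <- function(g, config = pest_config(), initial_offer = NULL) {
  stopifnot(inherits(g, "gamble"), inherits(config, "pest_config"))
  if (is.null(initial_offer))
    initial_offer <- stats::runif(1, config$safe_range[1],
                                  config$safe_range[2])
  stopifnot(initial_offer >= config$safe_range[1],
            initial_offer <= config$safe_range[2])
  structure(list(gamble = g, config = config,
                 offers = initial_offer, choices = character(0),
                 epsilon = config$epsilon_init,
                 epsilon_history = config$epsilon_init,
                 status = "running"),
            class = "pest_seq")
}

#' Advance a PEST sequence by one choice
#'
#' Records the choice on the current offer, computes the next offer with the
#' current epsilon (up after a gamble choice, down after a safe choice,
#' clamped to the representable range), then updates epsilon from the last
#' choice pair: doubled after two identical consecutive choices, halved
#' after a switch, active only once the fixed-epsilon trials have passed.
#' When epsilon drops below the exit rule the sequence converges and the
#' pending offer is discarded.
#'
#' @param seq a running `"pest_seq"`.
#' @param choice `"safe"` or `"gamble"`.
#' @return The updated `"pest_seq"`.
#' @export
pest_step <- function(seq, choice) {
  stopifnot(inherits(seq, "pest_seq"))
  if (seq$status != "running")
    stop("cannot step a ", seq$status, " PEST sequence", call. = FALSE)
  choice <- match.arg(choice, c("safe", "gamble"))
  seq$choices <- c(seq$choices, choice)
  t <- length(seq$choices)
  cfg <- seq$config
  step <- if (choice == "gamble") seq$epsilon else -seq$epsilon
  next_offer <- clamp(seq$offers[t] + step, cfg$safe_range[1],
                      cfg$safe_range[2])
  if (t > cfg$fixed_epsilon_trials) {
    seq$epsilon <- if (seq$choices[t] == seq$choices[t - 1])
      seq$epsilon * 2 else seq$epsilon / 2
  }
  seq$epsilon_history <- c(seq$epsilon_history, seq$epsilon)
  if (seq$epsilon < cfg$exit_rule) {
    seq$status <- "converged"
  } else if (t >= cfg$max_trials) {
    seq$status <- "exhausted"
  } else {
    seq$offers <- c(seq$offers, next_offer)
  }
  seq
}

#' Certainty equivalent of a converged PEST sequence
#'
#' The mean of the final two safe offers presented.
#'
#' @param seq a converged `"pest_seq"`.
#' @return Certainty equivalent in ml.
#' @export
pest_ce <- function(seq) {
  stopifnot(inherits(seq, "pest_seq"))
  if (seq$status != "converged")
    stop("PEST sequence has not converged (status: ", seq$status, ")",
         call. = FALSE)
  n <- length(seq$offers)
  mean(seq$offers[c(n - 1, n)])
}

#' Run a full PEST sequence against a choice oracle
#'
#' @param g the constant [gamble()].
#' @param oracle a function `(safe_ml, gamble) -> "safe"|"gamble"`, e.g.
#'   [agent_oracle()].
#' @param config a [pest_config()].
#' @param seed optional integer seed; seeds both the uniform initial offer
#'   and any randomness inside the oracle.
#' @return A list of class `"pest_result"`: `ce` (ml, `NA` if exhausted),
#'   `n_trials`, `status`, and the full `sequence` trace.
#' @export
run_pest <- function(g, oracle, config = pest_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- pest_start(g, config)
  while (seq$status == "running") {
    ch <- oracle(seq$offers[length(seq$offers)], g)
    seq <- pest_step(seq, ch)
  }
  structure(list(ce = if (seq$status == "converged") pest_ce(seq) else
                   NA_real_,
                 n_trials = length(seq$choices),
                 status = seq$status, sequence = seq, seed = seed),
            class = "pest_result")
}

#' @export
print.pest_result <- function(x, ...) {
  cat(sprintf("PEST: %s after %d trials; CE = %s ml\n", x$status,
              x$n_trials,
              if (is.na(x$ce)) "NA" else sprintf("%.3f", x$ce)))
  invisible(x)
}

#' Export a PEST trace as a data frame
#'
#' One row per completed trial: offer, choice and the epsilon in force
#' after the trial's update.
#'
#' @param x a `"pest_result"` or `"pest_seq"`.
#' @return A data frame with columns `trial`, `offer_ml`, `choice`,
#'   `epsilon_ml`.
#' @export
pest_trace <- function(x) {
  seq <- if (inherits(x, "pest_result")) x$sequence else x
  stopifnot(inherits(seq, "pest_seq"))
  n <- length(seq$choices)
  data.frame(trial = seq_len(n), offer_ml = seq$offers[seq_len(n)],
             choice = seq$choices,
             epsilon_ml = seq$epsilon_history[seq_len(n) + 1L])
}
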