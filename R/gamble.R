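#' Construct a finite lottery over juice volumes
#'
#' A gamble is a finite set of juice outcomes (ml) with probabilities summing
#' to one. The experiments use binary equiprobable gambles (each outcome
#' p = 0.5), but any finite lottery is supported; a degenerate gamble with a
#' single certain outcome represents a safe reward.
#'
#' @param outcomes numeric vector of outcome volumes in ml.
#' @param probs numeric vector of outcome probabilities; defaults to
#'   equiprobable outcomes. Must sum to 1 (tolerance 1e-9).
#' @return An object of class `"gamble"`.
#' @examples
#' g <- gamble(c(0.1, 0.4))        # low-value equiprobable gamble
#' expected_value(g)               # 0.25 ml
#' @export
gamble <- function(outcomes,
                   probs = rep(1 / length(outcomes), length(outcomes))) {
  stopifnot(is.numeric(outcomes), is.numeric(probs),
            length(outcomes) == length(probs), length(outcomes) >= 1L)
  if (any(probs < -1e-12)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  if (any(outcomes <= 0)) stop("outcome volumes must be positive (ml)")
  ord <- order(outcomes)
  structure(list(outcomes = outcomes[ord], probs = probs[ord]),
            class = "gamble")
}

#' @export
print.gamble <- function(x, ...) {
  cat("Gamble:",
      paste(sprintf("%.3g ml (p=%.3g)", x$outcomes, x$probs), collapse = ", "),
      "\n")
  invisible(x)
}

#' Expected value of a gamble
#'
#' Probability-weighted mean of the physical outcomes, in ml.
#'
#' @param g a [gamble()].
#' @return Expected value in ml.
#' @export
expected_value <- function(g) {
  stopifnot(inherits(g, "gamble"))
  sum(g$probs * g$outcomes)
}

#' Expected utility of a gamble
#'
#' Probability-weighted mean of the outcome utilities under a given utility
#' function.
#'
#' @param g a [gamble()].
#' @param u a utility representation: a fitted [utility_fn][fit_utility],
#'   a [ground_truth_utility()], or a plain function of volume.
#' @return Expected utility in util.
#' @export
expected_utility <- function(g, u) {
  stopifnot(inherits(g, "gamble"))
  sum(g$probs * eval_utility(u, g$outcomes))
}
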