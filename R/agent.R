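#' Parametric s-shaped ground-truth utility function
#'
#' The synthetic agent maximises expected utility under a known utility
#' function, so that every downstream estimate (certainty equivalents,
#' fractile points, spline fits, marginal utilities) can be compared against
#' a known truth. The family is a two-parameter beta CDF on the normalised
#' reward range: for shape parameters a, b > 1 it is convex at low volumes
#' and concave at high volumes, with the inflection at (a-1)/(a+b-2) on the
#' normalised domain.
#'
#' The defaults (a = 4, b = 2.77 on 0.1-1.2 ml) are chosen once to match
#' the qualitative profile reported for behaving subjects: the certainty
#' equivalent of the full-range equiprobable gamble falls at 0.76 ml, the
#' inflection sits at 0.63 of the range (right of midrange, an overall
#' risk-seeking subject), and the utility slope in midrange is roughly
#' twice the slope near either end, giving the characteristic inverted-U
#' of marginal utility across the three task gambles.
#'
#' @param shape_a,shape_b positive beta shape parameters.
#' @param domain length-2 numeric, reward range in ml.
#' @return An object of class `"ground_truth"`.
#' @examples
#' gt <- ground_truth_utility()
#' true_utility(0.76, gt)   # ~0.5 util
#' @export
ground_truth_utility <- function(shape_a = 4, shape_b = 2.77,
                                 domain = c(0.1, 1.2)) {
  stopifnot(shape_a > 0, shape_b > 0, length(domain) == 2L,
            domain[1] < domain[2])
  structure(list(shape_a = shape_a, shape_b = shape_b, domain = domain),
            class = "ground_truth")
}

#' Evaluate a ground-truth utility
#'
#' @param x volume(s) in ml, inside the domain.
#' @param g a [ground_truth_utility()].
#' @return Utility in `[0, 1]` util; strictly increasing in `x`.
#' @export
true_utility <- function(x, g) {
  stopifnot(inherits(g, "ground_truth"))
  stop_domain(x, g$domain)
  z <- (x - g$domain[1]) / diff(g$domain)
  stats::pbeta(clamp(z, 0, 1), g$shape_a, g$shape_b)
}

#' @export
eval_utility.ground_truth <- function(u, x) true_utility(x, u)

# derivative of the ground truth w.r.t. volume (util/ml)
true_marginal_utility <- function(x, g) {
  stopifnot(inherits(g, "ground_truth"))
  stop_domain(x, g$domain)
  z <- (x - g$domain[1]) / diff(g$domain)
  stats::dbeta(clamp(z, 0, 1), g$shape_a, g$shape_b) / diff(g$domain)
}

#' Parameters of the synthetic choosing agent
#'
#' The agent chooses between a safe reward and a gamble through a logistic
#' decision rule on the expected-utility difference, with an optional lapse
#' rate. A single EU-difference kernel generates monotone psychometric
#' curves in the safe volume, which is what the staircase and the
#' incentive-compatible procedure both need.
#'
#' @param utility a [ground_truth_utility()] (or any utility representation).
#' @param sensitivity positive logistic slope on the EU difference (1/util);
#'   `Inf` gives a deterministic expected-utility maximiser.
#' @param bias additive choice bias toward the safe option (util units).
#' @param lapse lapse rate in `[0, 0.5)`: the proportion of trials on which
#'   the agent guesses at random.
#' @return An object of class `"agent_params"`.
#' @export
agent_params <- function(utility = ground_truth_utility(),
                         sensitivity = 50, bias = 0, lapse = 0) {
  stopifnot(sensitivity > 0, lapse >= 0, lapse < 0.5, is.finite(bias))
  structure(list(utility = utility, sensitivity = sensitivity,
                 bias = bias, lapse = lapse),
            class = "agent_params")
}

#' Probability that the agent chooses the safe option
#'
#' `lapse/2 + (1 - lapse) * logistic(sensitivity * (u(safe) - EU(gamble)) + bias)`.
#'
#' @param safe safe reward volume in ml.
#' @param g a [gamble()].
#' @param params an [agent_params()].
#' @return Probability in `[0, 1]`.
#' @export
choice_prob_safe <- function(safe, g, params) {
  stopifnot(inherits(params, "agent_params"))
  du <- eval_utility(params$utility, safe) - expected_utility(g, params$utility)
  core <- if (is.infinite(params$sensitivity)) {
    ifelse(du > 0, 1, ifelse(du < 0, 0, stats::plogis(params$bias)))
  } else {
    stats::plogis(params$sensitivity * du + params$bias)
  }
  params$lapse / 2 + (1 - params$lapse) * core
}

#' Sample one choice between a safe reward and a gamble
#'
#' @inheritParams choice_prob_safe
#' @return `"safe"` or `"gamble"`.
#' @seealso [choice_prob_safe()] for the underlying probability;
#'   [agent_oracle()] to package the agent as a choice callback.
#' @export
agent_choose <- function(safe, g, params) {
  p <- choice_prob_safe(safe, g, params)
  if (stats::runif(1) < p) "safe" else "gamble"
}

#' Package an agent as a choice oracle
#'
#' Returns a function `(safe, gamble) -> "safe"|"gamble"` suitable for
#' [run_pest()] and [run_fractile()]. The oracle consumes the R random
#' number stream, so callers seed it.
#'
#' @param params an [agent_params()].
#' @export
agent_oracle <- function(params) {
  force(params)
  function(safe, g) agent_choose(safe, g, params)
}

# Closed-form certainty equivalent of a gamble under the ground truth:
# the volume whose true utility equals the gamble's expected utility.
true_certainty_equivalent <- function(g, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  eu <- expected_utility(g, gt)
  gt$domain[1] + diff(gt$domain) * stats::qbeta(eu, gt$shape_a, gt$shape_b)
}
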