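#' Cumulative distribution function of a finite lottery
#'
#' Right-continuous step CDF on the lottery's support.
#'
#' @param g a [gamble()].
#' @return A list of class `"lottery_cdf"`: `support` (sorted unique
#'   outcomes) and `cdf` (cumulative probability at each support point).
#' @export
lottery_cdf <- function(g) {
  stopifnot(inherits(g, "gamble"))
  support <- sort(unique(g$outcomes))
  p <- vapply(support, function(s) sum(g$probs[g$outcomes == s]),
              numeric(1))
  structure(list(support = support, cdf = cumsum(p)), class = "lottery_cdf")
}

# CDF values of a lottery evaluated at arbitrary points (right-continuous).
cdf_at <- function(g, x) {
  vapply(x, function(v) sum(g$probs[g$outcomes <= v + 1e-12]), numeric(1))
}

#' First-order stochastic dominance between two lotteries
#'
#' Lottery `a` first-order stochastically dominates `b` when its CDF lies
#' weakly below `b`'s everywhere, strictly somewhere: there is nothing to
#' lose by choosing `a`, and any chooser with a strictly increasing value
#' function prefers it. Decided exactly on the union of supports with a
#' strictness tolerance of 1e-12 on probabilities.
#'
#' @param a,b [gamble()] objects.
#' @return `"a-dominates"`, `"b-dominates"`, `"none"`, or `"identical"`.
#' @export
fosd <- function(a, b) {
  stopifnot(inherits(a, "gamble"), inherits(b, "gamble"))
  grid <- sort(unique(c(a$outcomes, b$outcomes)))
  fa <- cdf_at(a, grid)
  fb <- cdf_at(b, grid)
  tol <- 1e-12
  if (all(abs(fa - fb) <= tol)) return("identical")
  a_weak <- all(fa <= fb + tol)
  b_weak <- all(fb <= fa + tol)
  if (a_weak && any(fa < fb - tol)) return("a-dominates")
  if (b_weak && any(fb < fa - tol)) return("b-dominates")
  "none"
}

#' Is lottery `a` a mean-preserving spread of lottery `b`?
#'
#' True when both lotteries have the same mean and `a` is strictly riskier:
#' the integral of `a`'s CDF weakly majorises that of `b` everywhere, with
#' strict excess somewhere. A mean-preserving spread leaves expected
#' utility unchanged under linear utility but is dispreferred under
#' concavity and preferred under convexity.
#'
#' @param a,b [gamble()] objects.
#' @return Logical.
#' @export
is_mean_preserving_spread <- function(a, b) {
  stopifnot(inherits(a, "gamble"), inherits(b, "gamble"))
  tol <- 1e-12
  if (abs(expected_value(a) - expected_value(b)) > 1e-9) return(FALSE)
  grid <- sort(unique(c(a$outcomes, b$outcomes)))
  if (length(grid) < 2) return(FALSE)
  fa <- cdf_at(a, grid)
  fb <- cdf_at(b, grid)
  # integrated CDFs between consecutive support points (step functions)
  widths <- diff(grid)
  ia <- cumsum(fa[-length(fa)] * widths)
  ib <- cumsum(fb[-length(fb)] * widths)
  all(ia >= ib - tol) && any(ia > ib + tol)
}

#' Predicted preference between equal-mean lotteries under a utility
#' function
#'
#' Second-order stochastic dominance among equal-mean lotteries is decided
#' by risk attitude: a concave utility function prefers the less risky
#' lottery, a convex one the riskier. The prediction is simply the lottery
#' with the higher expected utility; exact ties (e.g. linear utility) are
#' flagged.
#'
#' @param a,b equal-mean [gamble()] objects (means within 1e-9 ml).
#' @param u a utility representation.
#' @return A list: `preferred` (`"a"`, `"b"`, or `"tie"`), `eu_a`, `eu_b`.
#' @export
sosd_preference <- function(a, b, u) {
  stopifnot(inherits(a, "gamble"), inherits(b, "gamble"))
  if (abs(expected_value(a) - expected_value(b)) > 1e-9)
    stop("second-order comparison requires equal-mean lotteries")
  eu_a <- expected_utility(a, u)
  eu_b <- expected_utility(b, u)
  preferred <- if (abs(eu_a - eu_b) < 1e-12) "tie" else
    if (eu_a > eu_b) "a" else "b"
  list(preferred = preferred, eu_a = eu_a, eu_b = eu_b)
}
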