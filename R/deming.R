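#' Deming (errors-in-both-variables) regression
#'
#' Orthogonal regression of `y` on `x` with a fixed error-variance ratio,
#' used for agreement between predicted and measured quantities where both
#' axes carry measurement error. At variance ratio 1 the fit is symmetric:
#' swapping the axes gives the reciprocal slope. A 95% confidence interval
#' for the slope is obtained by leave-one-out jackknife.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param variance_ratio ratio of the y to x error variances (default 1).
#' @param conf confidence level for the jackknife band.
#' @return An object of class `"deming_fit"`: `slope`, `intercept`,
#'   `slope_ci`, `variance_ratio`, `n`.
#' @export
deming <- function(x, y, variance_ratio = 1, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3, variance_ratio > 0)
  est <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    d <- variance_ratio
    if (abs(sxy) < 1e-300) return(c(NA_real_, NA_real_))
    slope <- (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) /
      (2 * sxy)
    c(slope, mean(y) - slope * mean(x))
  }
  fit <- est(x, y)
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) est(x[-i], y[-i])[1], numeric(1))
  ok <- is.finite(jack)
  se <- if (sum(ok) >= 3) {
    m <- mean(jack[ok])
    sqrt((sum(ok) - 1) / sum(ok) * sum((jack[ok] - m)^2))
  } else NA_real_
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(slope = fit[1], intercept = fit[2],
                 slope_ci = fit[1] + c(-1, 1) * z * se,
                 slope_se = se, variance_ratio = variance_ratio, n = n),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (n = %d, ratio = %g): slope = %.3f [%.3f, %.3f], intercept = %.3f\n",
    x$n, x$variance_ratio, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept))
  invisible(x)
}

#' Default held-out validation gambles
#'
#' Twelve binary equiprobable gambles spanning the reward range, none of
#' which coincides with the fractile construction gambles, used to test the
#' fitted utility function out of sample.
#'
#' @param domain reward range in ml.
#' @return List of 12 [gamble()] objects.
#' @export
default_validation_gambles <- function(domain = c(0.1, 1.2)) {
  lo <- domain[1]; hi <- domain[2]; r <- hi - lo
  pairs <- rbind(c(0.00, 0.27), c(0.09, 0.36), c(0.18, 0.45),
                 c(0.27, 0.55), c(0.36, 0.64), c(0.45, 0.73),
                 c(0.55, 0.82), c(0.64, 0.91), c(0.73, 1.00),
                 c(0.09, 0.73), c(0.18, 0.91), c(0.00, 0.64))
  lapply(seq_len(nrow(pairs)),
         function(i) gamble(round(lo + r * pairs[i, ], 3)))
}

#' Out-of-sample validation of a fitted utility function
#'
#' For gambles not used in constructing the function, compares predicted
#' expected utilities with the utilities of behaviourally measured
#' certainty equivalents via Deming regression (variance ratio 1). Because
#' both quantities co-vary with the gambles' expected values, a second fit
#' is run after removing the linear EV component from both axes by
#' ordinary regression on EV; the residual association isolates the
#' contribution of the utility function's curvature. Association on the
#' residuals is additionally summarised by a Pearson correlation, whose
#' test is well defined even when the residual signal is absent (the
#' errors-in-variables slope is not identified in that null case).
#'
#' Note that because one and the same fitted function maps both axes, any
#' wiggle in the fit induces shared deviations from the EV line in the
#' predicted and observed values; even for a truth with no curvature the
#' residual association therefore exceeds its nominal false-positive
#' rate. Comparisons between competing truths should be made on the
#' strength of the residual association, not on raw significance alone.
#'
#' @param u a fitted `"utility_fn"`.
#' @param gambles list of held-out [gamble()] objects (>= 3).
#' @param measured_ces numeric vector of measured CEs (ml), one per gamble.
#' @return A list of class `"validation_fit"`: `fit` (Deming of measured-CE
#'   utility on predicted EU), `residual_fit` (Deming on EV-residualised
#'   axes), `residual_cor` (Pearson test on the residuals), plus the
#'   per-gamble table.
#' @export
validate_out_of_sample <- function(u, gambles, measured_ces) {
  stopifnot(length(gambles) == length(measured_ces), length(gambles) >= 3)
  predicted <- vapply(gambles, expected_utility, numeric(1), u = u)
  observed <- eval_utility(u, clamp(measured_ces, u$domain[1], u$domain[2]))
  ev <- vapply(gambles, expected_value, numeric(1))
  fit <- deming(predicted, observed)
  rx <- stats::resid(stats::lm(predicted ~ ev))
  ry <- stats::resid(stats::lm(observed ~ ev))
  residual_fit <- deming(rx, ry)
  ct <- stats::cor.test(rx, ry)
  structure(list(fit = fit, residual_fit = residual_fit,
                 residual_cor = list(rho = unname(ct$estimate),
                                     p = ct$p.value),
                 table = data.frame(ev = ev, predicted_eu = predicted,
                                    measured_ce = measured_ces,
                                    observed_utility = observed)),
            class = "validation_fit")
}

#' @export
print.validation_fit <- function(x, ...) {
  cat("Out-of-sample validation\n  full: ")
  print(x$fit)
  cat("  EV-residualised: ")
  print(x$residual_fit)
  cat(sprintf("  residual Pearson rho = %.3f (p = %.3g)\n",
              x$residual_cor$rho, x$residual_cor$p))
  invisible(x)
}
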