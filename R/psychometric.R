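#' Logistic psychometric fit of safe-versus-gamble choices
#'
#' Fits `P(safe choice) = 1 / (1 + exp(-(alpha + beta * safe_ml)))` by
#' maximum likelihood, where alpha measures choice bias and beta the
#' sensitivity (slope). The certainty equivalent is the safe volume at
#' choice indifference (50% choice), `-alpha/beta`. This is the
#' incentive-compatible counterpart of the PEST estimate: the tested safe
#' volumes are set independently of the subject's choice history.
#'
#' Complete separation (all choices flip at one point, infinite slope) makes
#' the MLE undefined; in that case the CE is the midpoint between the
#' highest safe volume always rejected and the lowest always accepted, and
#' the fit is flagged.
#'
#' @param choices data frame with columns `safe_ml` and logical (or 0/1)
#'   `chose_safe`; requires at least two distinct safe levels with both
#'   responses represented overall.
#' @return An object of class `"psychometric_fit"`: `alpha`, `beta`
#'   (per ml), `ce` (ml), `se_alpha`, `se_beta`, and `flag`
#'   (`"ok"`, `"separation"`, or `"flat"` when beta is not significantly
#'   positive and the 50% point is therefore unidentified).
#' @export
fit_psychometric <- function(choices) {
  stopifnot(is.data.frame(choices),
            all(c("safe_ml", "chose_safe") %in% names(choices)))
  y <- as.integer(choices$chose_safe)
  x <- choices$safe_ml
  if (length(unique(x)) < 2)
    stop("need at least two distinct safe levels")
  if (all(y == 1) || all(y == 0))
    stop("both responses must be represented")
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial()))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  alpha <- unname(co[1]); beta <- unname(co[2])
  separated <- !fit$converged || abs(beta) > 1e3 || any(se > 1e3)
  flag <- "ok"
  ce <- -alpha / beta
  if (separated) {
    flag <- "separation"
    lo <- suppressWarnings(max(x[y == 0]))
    hi <- suppressWarnings(min(x[y == 1]))
    ce <- mean(c(lo, hi))
    warning("complete separation; CE interpolated at the response midpoint",
            call. = FALSE)
  } else if (beta <= 0 || beta < 1.96 * se[2]) {
    # slope not significantly positive: the 50% point is unidentified
    flag <- "flat"
    ce <- NA_real_
  }
  structure(list(alpha = alpha, beta = beta, ce = ce,
                 se_alpha = unname(se[1]), se_beta = unname(se[2]),
                 flag = flag, n = length(y)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit (n = %d): alpha = %.3f, beta = %.3f /ml, CE = %s ml%s\n",
    x$n, x$alpha, x$beta,
    if (is.na(x$ce)) "NA" else sprintf("%.3f", x$ce),
    if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Binomial logistic regression of trialwise choice determinants
#'
#' Assesses the effect on the safe/gamble choice of the gamble value, the
#' safe value, the accumulated daily reward, the prior outcome, and the
#' position of the safe cue on the screen. Used to check that a subject's
#' choices are driven by the offered values rather than by side biases or
#' history.
#'
#' @param trials data frame with columns `chose_safe`, `gamble_value`,
#'   `safe_ml`, `accumulated_ml`, `prior_outcome`, `safe_side` (as produced
#'   by [simulate_choice_session()]).
#' @return An object of class `"choice_regression"`: a coefficient table
#'   (estimate, SE, z, Wald p per regressor) plus a `flag` that is
#'   `"separation"` when the fit is degenerate.
#' @export
choice_determinant_regression <- function(trials) {
  needed <- c("chose_safe", "gamble_value", "safe_ml", "accumulated_ml",
              "prior_outcome", "safe_side")
  stopifnot(is.data.frame(trials))
  missing <- setdiff(needed, names(trials))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  X <- stats::model.matrix(
    ~ gamble_value + safe_ml + accumulated_ml + prior_outcome + safe_side,
    data = trials)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- as.integer(trials$chose_safe)
  if (all(y == y[1])) {
    res <- structure(list(table = NULL, flag = "separation"),
                     class = "choice_regression")
    return(res)
  }
  fit <- suppressWarnings(stats::glm(
    chose_safe ~ gamble_value + safe_ml + accumulated_ml + prior_outcome +
      safe_side,
    family = stats::binomial(), data = trials))
  sm <- stats::summary.glm(fit)$coefficients
  flag <- if (!fit$converged || any(abs(sm[, "Estimate"]) > 1e3))
    "separation" else "ok"
  tab <- data.frame(term = rownames(sm),
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    z = sm[, "z value"],
                    p = sm[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, flag = flag), class = "choice_regression")
}

#' @export
print.choice_regression <- function(x, ...) {
  if (x$flag == "separation" && is.null(x$table)) {
    cat("Choice regression: degenerate (all choices identical)\n")
  } else {
    cat("Choice-determinant logistic regression",
        if (x$flag != "ok") paste0(" [", x$flag, "]"), "\n")
    print(x$table, digits = 3)
  }
  invisible(x)
}
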