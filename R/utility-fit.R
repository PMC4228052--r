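#' Fit a monotone piecewise-cubic utility function to fractile points
#'
#' Least-squares fit of a cubic spline (order 4) with a small number of
#' free interior knots to measured (volume, utility) points. Monotonicity
#' is enforced exactly by constraining the B-spline coefficients to be
#' nondecreasing -- a standard sufficient condition for a nondecreasing
#' spline -- which encodes the economic assumption that more juice never
#' has less utility (weakly increasing, nonsatiating in the tested range).
#' Knot positions are free parameters, optimised by Nelder-Mead from
#' several starts (one equispaced, the rest randomised under a fixed seed);
#' for each candidate knot set the coefficients solve a bound-constrained
#' linear least-squares problem. After fitting, the utility axis is
#' renormalised so the fitted function is exactly 0 and 1 at the domain
#' ends.
#'
#' @param points data frame with columns `volume` (ml) and `utility`
#'   (util), at least 5 rows spanning the domain (as produced by
#'   [run_fractile()]).
#' @param n_knots number of free interior knots (default 3).
#' @param domain utility domain in ml; defaults to the range of the points.
#' @param n_starts multistart count for knot placement.
#' @param seed seed for the randomised starts (local to the fit; the
#'   global RNG state is restored).
#' @return An object of class `"utility_fn"`: full knot vector, B-spline
#'   coefficients (normalised to 0/1 at the ends), domain, and the
#'   residual sum of squares of the unnormalised fit.
#' @seealso [marginal_utility()], [certainty_equivalent()],
#'   [average_sessions()]
#' @export
fit_utility <- function(points, n_knots = 3, domain = NULL, n_starts = 5,
                        seed = 1L) {
  stopifnot(is.data.frame(points),
            all(c("volume", "utility") %in% names(points)))
  x <- points$volume
  y <- points$utility
  if (length(x) < 5) stop("need at least 5 utility points")
  if (length(unique(x)) < 5) stop("need at least 5 distinct volumes")
  if (is.null(domain)) domain <- range(x)
  stopifnot(all(x >= domain[1] - 1e-9), all(x <= domain[2] + 1e-9))
  x <- clamp(x, domain[1], domain[2])
  ord <- 4L
  k <- n_knots
  nb <- k + ord                           # basis dimension
  map <- matrix(0, nb, nb)                # p = (a, d...) -> coefficients
  map[, 1] <- 1
  for (j in 2:nb) map[j:nb, j] <- 1

  # near-interpolation fits are tied at zero residual for many knot
  # placements; a very small curvature penalty breaks the ties toward the
  # smoothest monotone solution without biasing fits of noisy data
  pen_grid <- seq(domain[1], domain[2], length.out = 50)
  pen_w <- 1e-6 / length(pen_grid)
  inner_fit <- function(interior) {
    knots <- c(rep(domain[1], ord), interior, rep(domain[2], ord))
    B <- splines::splineDesign(knots, x, ord = ord) %*% map
    B2 <- splines::splineDesign(knots, pen_grid, ord = ord,
                                derivs = rep(2L, length(pen_grid))) %*% map
    obj <- function(p) {
      r <- drop(B %*% p) - y
      sum(r^2) + pen_w * sum(drop(B2 %*% p)^2)
    }
    grad <- function(p)
      drop(2 * crossprod(B, drop(B %*% p) - y) +
             2 * pen_w * crossprod(B2, drop(B2 %*% p)))
    p0 <- c(min(y), rep(max(1e-3, diff(range(y)) / (nb - 1)), nb - 1))
    fit <- stats::optim(p0, obj, grad, method = "L-BFGS-B",
                        lower = c(-Inf, rep(0, nb - 1)),
                        control = list(maxit = 500, factr = 1e4))
    theta <- drop(map %*% fit$par)
    list(theta = theta, rss = sum((drop(B %*% fit$par) - y)^2),
         penalized = fit$value, knots = knots)
  }

  knots_from_z <- function(z) {
    w <- exp(c(z, 0))
    gaps <- w / sum(w)
    domain[1] + diff(domain) * cumsum(gaps)[seq_len(k)]
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  starts <- c(list(rep(0, k)),
              replicate(max(0, n_starts - 1),
                        stats::rnorm(k, 0, 1), simplify = FALSE))
  best <- NULL
  for (z0 in starts) {
    opt <- stats::optim(z0,
                        function(z) inner_fit(knots_from_z(z))$penalized,
                        method = "Nelder-Mead",
                        control = list(maxit = 150, reltol = 1e-9))
    cand <- inner_fit(knots_from_z(opt$par))
    if (is.null(best) || cand$penalized < best$penalized) best <- cand
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  theta <- best$theta
  span <- theta[nb] - theta[1]
  if (span < 1e-8) stop("degenerate fit: utility function is flat")
  theta <- (theta - theta[1]) / span
  structure(list(knots = best$knots, theta = theta, order = ord,
                 domain = domain, rss = best$rss,
                 interior_knots = best$knots[(ord + 1):(ord + k)]),
            class = "utility_fn")
}

# Build a utility_fn directly from coefficients (internal).
utility_fn_from_theta <- function(theta, interior, domain, ord = 4L) {
  knots <- c(rep(domain[1], ord), interior, rep(domain[2], ord))
  structure(list(knots = knots, theta = theta, order = ord,
                 domain = domain, rss = NA_real_,
                 interior_knots = interior),
            class = "utility_fn")
}

#' Exactly linear utility function
#'
#' The normalised linear map `(x - lo) / (hi - lo)` represented as a
#' `"utility_fn"` spline, useful as a risk-neutral reference.
#'
#' @param domain reward range in ml.
#' @param n_knots interior knot count (kept for structural parity with
#'   fitted functions).
#' @export
linear_utility <- function(domain = c(0.1, 1.2), n_knots = 3) {
  ord <- 4L
  interior <- domain[1] + diff(domain) * seq_len(n_knots) / (n_knots + 1)
  knots <- c(rep(domain[1], ord), interior, rep(domain[2], ord))
  nb <- n_knots + ord
  # Greville abscissae reproduce the identity, then normalise to [0, 1]
  grev <- vapply(seq_len(nb), function(i) mean(knots[(i + 1):(i + 3)]),
                 numeric(1))
  theta <- (grev - domain[1]) / diff(domain)
  utility_fn_from_theta(theta, interior, domain)
}

#' Evaluate a fitted utility function (or its derivatives)
#'
#' @param object a `"utility_fn"`.
#' @param x volumes in ml, inside the domain.
#' @param deriv derivative order (0, 1 or 2).
#' @param ... unused.
#' @return Numeric vector: util for `deriv = 0`, util/ml for `deriv = 1`.
#' @export
predict.utility_fn <- function(object, x, deriv = 0, ...) {
  stop_domain(x, object$domain)
  x <- clamp(x, object$domain[1], object$domain[2])
  B <- splines::splineDesign(object$knots, x, ord = object$order,
                             derivs = rep(deriv, length(x)))
  drop(B %*% object$theta)
}

#' @export
eval_utility.utility_fn <- function(u, x) predict.utility_fn(u, x)

#' @export
print.utility_fn <- function(x, ...) {
  cat(sprintf(
    "Monotone cubic-spline utility on [%.3g, %.3g] ml; interior knots: %s\n",
    x$domain[1], x$domain[2],
    paste(sprintf("%.3f", x$interior_knots), collapse = ", ")))
  invisible(x)
}

#' @export
plot.utility_fn <- function(x, n = 200, ...) {
  xs <- seq(x$domain[1], x$domain[2], length.out = n)
  graphics::plot(xs, predict(x, xs), type = "l", xlab = "volume (ml)",
                 ylab = "utility (util)", ...)
  invisible(x)
}

#' Marginal utility: first derivative of the utility function
#'
#' @param u a `"utility_fn"` (or [ground_truth_utility()]).
#' @param x volumes in ml.
#' @return Marginal utility in util/ml, nonnegative by the monotonicity
#'   constraint (tiny negative rounding is clipped to zero).
#' @export
marginal_utility <- function(u, x) {
  if (inherits(u, "ground_truth")) return(true_marginal_utility(x, u))
  stopifnot(inherits(u, "utility_fn"))
  pmax(0, predict(u, x, deriv = 1))
}

#' Averaged slope of the utility function over an interval
#'
#' The chord slope `(u(to) - u(from)) / (to - from)`, the discrete
#' counterpart of marginal utility used when a prediction error spans a
#' finite reward interval.
#'
#' @param u a utility representation.
#' @param x_from,x_to interval ends in ml, `x_from < x_to`.
#' @return Slope in util/ml.
#' @export
interval_marginal_utility <- function(u, x_from, x_to) {
  if (any(x_to - x_from <= 0)) stop("zero-width or reversed interval")
  (eval_utility(u, x_to) - eval_utility(u, x_from)) / (x_to - x_from)
}

#' Certainty equivalent of a gamble under a utility function
#'
#' The safe volume whose utility equals the gamble's expected utility,
#' found by monotone root-finding (unique when the function is strictly
#' increasing at the target level). On a flat segment the midpoint of the
#' indifference interval is returned with attribute `flat = TRUE`.
#'
#' @param g a [gamble()].
#' @param u a utility representation.
#' @param tol root-finder tolerance on volume, ml.
#' @return Certainty equivalent in ml.
#' @export
certainty_equivalent <- function(g, u, tol = 1e-9) {
  if (inherits(u, "ground_truth")) return(true_certainty_equivalent(g, u))
  stopifnot(inherits(u, "utility_fn"))
  target <- expected_utility(g, u)
  dom <- u$domain
  f <- function(x) predict(u, x) - target
  if (f(dom[1]) > tol) return(structure(dom[1], flat = FALSE))
  if (f(dom[2]) < -tol) return(structure(dom[2], flat = FALSE))
  root <- stats::uniroot(f, dom, tol = tol)$root
  if (predict(u, root, deriv = 1) < 1e-8) {
    # flat segment at the target level: bracket it and return the midpoint
    grid <- seq(dom[1], dom[2], length.out = 513)
    hit <- grid[abs(predict(u, grid) - target) < 1e-7]
    if (length(hit) >= 2)
      return(structure(mean(range(c(hit, root))), flat = TRUE))
  }
  structure(root, flat = FALSE)
}

#' Pointwise average and SD band of several session fits
#'
#' Utility functions measured on different days are combined pointwise on
#' an evaluation grid: the band is the across-session mean plus/minus one
#' sample SD.
#'
#' @param fits list of `"utility_fn"` objects sharing one domain.
#' @param grid evaluation volumes; defaults to 200 points over the domain.
#' @return An object of class `"utility_band"`: `grid`, `mean`, `sd`, `n`.
#' @export
average_sessions <- function(fits, grid = NULL) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "utility_fn")))
  dom <- fits[[1]]$domain
  same <- vapply(fits, function(f) isTRUE(all.equal(f$domain, dom)),
                 logical(1))
  if (!all(same)) stop("fits have mismatched domains")
  if (is.null(grid)) grid <- seq(dom[1], dom[2], length.out = 200)
  M <- vapply(fits, predict, numeric(length(grid)), x = grid)
  structure(list(grid = grid, mean = rowMeans(M),
                 sd = apply(M, 1, stats::sd), n = length(fits)),
            class = "utility_band")
}

#' @export
print.utility_band <- function(x, ...) {
  cat(sprintf("Session-averaged utility curve (n = %d sessions, %d grid points)\n",
              x$n, length(x$grid)))
  invisible(x)
}
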