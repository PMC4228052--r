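# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed from a master seed
#'
#' Each pipeline stage draws its randomness from its own seed so that any
#' stage can be re-run in isolation. Child seeds are a deterministic hash of
#' the master seed and a stage label, kept below 2^31 so they are valid R
#' integer seeds.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"pest"`.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(master) %% 2147483647
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Evaluate any supported utility representation at volumes x (vectorised).
# Methods exist for fitted spline utilities, parametric ground truths and
# plain R functions.
eval_utility <- function(u, x) UseMethod("eval_utility")

#' @export
eval_utility.function <- function(u, x) u(x)

stop_domain <- function(x, domain) {
  if (any(x < domain[1] - 1e-12 | x > domain[2] + 1e-12)) {
    stop("volume outside the utility domain [", domain[1], ", ", domain[2],
         "] ml", call. = FALSE)
  }
  invisible(x)
}
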