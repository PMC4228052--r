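# Plain-text serialisation: spike trains, utility fits, configs.

#' Write spike trains to a plain-text file
#'
#' One line per trial holding space-separated spike times in seconds
#' (an empty line for a trial without spikes); `#`-prefixed header lines
#' carry metadata. The format round-trips exactly at the printed precision.
#'
#' @param trains list of [spike_train][generate_response] objects or
#'   numeric vectors.
#' @param path output file path.
#' @param digits decimal digits for the times (default 6, i.e. 1 µs).
#' @export
write_spike_trains <- function(trains, path, digits = 6) {
  lines <- c(sprintf("# spike times (s), one trial per line; n_trials=%d",
                     length(trains)))
  body <- vapply(trains, function(tr) {
    t <- if (inherits(tr, "spike_train")) tr$times else as.numeric(tr)
    paste(formatC(t, digits = digits, format = "f"), collapse = " ")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#'
#' @param path file path.
#' @return List of numeric vectors of spike times (s).
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lapply(lines, function(l) {
    if (!nzchar(trimws(l))) return(numeric(0))
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
}

#' Serialise a fitted utility function to JSON
#'
#' Stores knots, coefficients and domain so the piecewise cubic can be
#' reconstructed exactly.
#'
#' @param u a `"utility_fn"`.
#' @param path output path.
#' @export
write_utility_fn <- function(u, path) {
  stopifnot(inherits(u, "utility_fn"))
  jsonlite::write_json(list(knots = u$knots, theta = u$theta,
                            order = u$order, domain = u$domain),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a utility function written by [write_utility_fn()]
#'
#' @param path file path.
#' @return A `"utility_fn"`.
#' @export
read_utility_fn <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  ord <- as.integer(o$order)
  k <- length(o$knots) - 2L * ord
  structure(list(knots = o$knots, theta = o$theta, order = ord,
                 domain = o$domain, rss = NA_real_,
                 interior_knots = if (k > 0)
                   o$knots[(ord + 1):(ord + k)] else numeric(0)),
            class = "utility_fn")
}
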