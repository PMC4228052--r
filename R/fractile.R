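#' Build the fractile bisection schedule
#'
#' The fractile method maps measured certainty equivalents onto a fixed
#' utility axis by bisection. The root gamble spans the whole reward range;
#' its CE receives the utility level 0.5 (the mean of the anchor levels 0
#' and 1). Each further step uses previously measured CEs as outcomes of new
#' gambles that bisect the lowest and highest remaining subintervals of the
#' utility axis, so depth 3 yields levels 0.5, 0.25, 0.75, 0.125, 0.875 and
#' the edge refinements add 1/16 and 15/16 (0.063 and 0.938 at 3 decimals).
#' Together with the anchors this gives the seven to nine utility points a
#' session produces.
#'
#' @param domain reward range in ml, `c(lo, hi)`; `u(lo) = 0`,
#'   `u(hi) = 1`.
#' @param depth number of bisection generations (>= 1).
#' @param edge_refine if `TRUE`, add one extra bisection of the outermost
#'   subintervals beyond `depth`.
#' @return A data frame of class `"fractile_schedule"`, in measurement
#'   order, with columns `node`, `lo_level`, `hi_level`, `level`
#'   (= mean of the outcome levels) and `level_3dp`.
#' @examples
#' sched <- build_fractile_schedule(depth = 3)
#' sched$level_3dp   # 0.5, 0.25, 0.75, 0.125, 0.875, 0.063, 0.938
#' @export
build_fractile_schedule <- function(domain = c(0.1, 1.2), depth = 3,
                                    edge_refine = TRUE) {
  stopifnot(depth >= 1)
  nodes <- data.frame(lo_level = 0, hi_level = 1)
  if (depth >= 2) {
    for (d in 2:depth) {
      # bisect the lowest and highest remaining subintervals of the axis
      nodes <- rbind(nodes,
                     data.frame(lo_level = 0, hi_level = (1 / 2)^(d - 1)),
                     data.frame(lo_level = 1 - (1 / 2)^(d - 1),
                                hi_level = 1))
    }
  }
  if (edge_refine) {
    lo_hi <- (1 / 2)^depth
    hi_lo <- 1 - (1 / 2)^depth
    nodes <- rbind(nodes,
                   data.frame(lo_level = 0, hi_level = lo_hi),
                   data.frame(lo_level = hi_lo, hi_level = 1))
  }
  nodes$level <- (nodes$lo_level + nodes$hi_level) / 2
  nodes$level_3dp <- floor(nodes$level * 1000 + 0.5) / 1000  # half-up
  nodes <- cbind(node = seq_len(nrow(nodes)), nodes)
  attr(nodes, "domain") <- domain
  class(nodes) <- c("fractile_schedule", "data.frame")
  nodes
}

#' Run the fractile procedure against a CE oracle
#'
#' Walks the schedule in order. Each node's gamble is the equiprobable
#' lottery between the volumes already assigned to its outcome levels
#' (anchors for levels 0 and 1, previously measured mean CEs otherwise).
#' The node's CE is measured `repeats` times and the mean CE both defines
#' the node's utility point and seeds descendant gambles.
#'
#' @param ce_oracle function `(gamble) -> ml`, one CE measurement; e.g. a
#'   wrapper around [run_pest()] with a synthetic agent, or a noiseless
#'   closed-form oracle.
#' @param schedule a [build_fractile_schedule()].
#' @param repeats CE measurements per node (>= 1).
#' @return A data frame of utility points with columns `volume` (ml),
#'   `utility` (util), `n_repeats`, `node` (0 for the anchors), and
#'   `ce_sd` (SD across repeats, `NA` for anchors), sorted by volume. The
#'   anchor points (domain ends at utility 0 and 1) are always included.
#' @export
run_fractile <- function(ce_oracle, schedule = build_fractile_schedule(),
                         repeats = 1) {
  stopifnot(is.function(ce_oracle), inherits(schedule, "fractile_schedule"),
            repeats >= 1)
  domain <- attr(schedule, "domain")
  key <- function(lv) sprintf("%.10f", lv)
  vol_at <- as.list(stats::setNames(c(domain[1], domain[2]), key(c(0, 1))))
  pts <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    lo <- vol_at[[key(schedule$lo_level[i])]]
    hi <- vol_at[[key(schedule$hi_level[i])]]
    if (is.null(lo) || is.null(hi))
      stop("schedule node ", schedule$node[i],
           " references an unmeasured level")
    g <- gamble(c(lo, hi))
    ces <- vapply(seq_len(repeats), function(r) {
      ce <- ce_oracle(g)
      if (is.na(ce)) stop("CE measurement failed (PEST exhausted) at node ",
                          schedule$node[i], call. = FALSE)
      ce
    }, numeric(1))
    vol_at[[key(schedule$level[i])]] <- mean(ces)
    pts[[i]] <- data.frame(volume = mean(ces),
                           utility = schedule$level[i],
                           n_repeats = repeats, node = schedule$node[i],
                           ce_sd = if (repeats > 1) stats::sd(ces) else
                             NA_real_)
  }
  out <- rbind(data.frame(volume = domain, utility = c(0, 1),
                          n_repeats = NA_integer_, node = 0L,
                          ce_sd = NA_real_),
               do.call(rbind, pts))
  out[order(out$volume), , drop = FALSE]
}

#' Closed-form CE oracle for a ground-truth utility
#'
#' Returns the exact certainty equivalent of any gamble under a known
#' ground truth: useful for testing the fractile machinery without
#' measurement noise.
#'
#' @param gt a [ground_truth_utility()].
#' @return A function `(gamble) -> ml`.
#' @export
exact_ce_oracle <- function(gt) {
  force(gt)
  function(g) true_certainty_equivalent(g, gt)
}

#' PEST-based CE oracle for a synthetic agent
#'
#' Packages a synthetic agent plus PEST configuration as a CE oracle for
#' [run_fractile()]. Each call runs one full PEST sequence (consuming the
#' R random stream). A sequence that hits the trial cap without meeting
#' the exit rule is re-run from a fresh random starting offer -- the
#' session-control policy an experimenter applies when a staircase fails
#' to terminate -- up to `attempts` times; only then is `NA` returned.
#'
#' @param agent an [agent_params()].
#' @param config a [pest_config()].
#' @param attempts maximum staircase runs per CE measurement.
#' @return A function `(gamble) -> ml`.
#' @export
pest_ce_oracle <- function(agent, config = pest_config(), attempts = 5) {
  oracle <- agent_oracle(agent)
  function(g) {
    for (i in seq_len(attempts)) {
      res <- run_pest(g, oracle, config)
      if (res$status == "converged") return(res$ce)
    }
    NA_real_
  }
}
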