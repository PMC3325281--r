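#' Strategy outcome (cost, effectiveness)
#'
#' @param strategy Strategy label.
#' @param cost Total cost in dollars, `>= 0`.
#' @param qaly Total QALYs, `>= 0`.
#' @return An object of class `strategy_outcome`.
#' @export
strategy_outcome <- function(strategy, cost, qaly) {
  if (cost < 0 || qaly < 0) stop("cost and qaly must be non-negative")
  structure(list(strategy = strategy, cost = cost, qaly = qaly),
            class = "strategy_outcome")
}

#' Incremental cost, effectiveness and ICER
#'
#' \eqn{\Delta C = C_a - C_b}, \eqn{\Delta E = E_a - E_b},
#' \eqn{ICER = \Delta C / \Delta E}. When \eqn{\Delta E = 0} the ICER is
#' undefined and returned as `NA` with `icer_defined = FALSE` (a flagged
#' value, not an error).
#'
#' @param a,b [strategy_outcome()] objects (a vs b).
#' @return A list with `delta_cost`, `delta_qaly`, `icer`, `icer_defined`.
#' @examples
#' incremental(strategy_outcome("RT+TMZ", 32562.4, 1.09),
#'             strategy_outcome("RT", 7234.0, 0.80))
#' @export
incremental <- function(a, b) {
  stopifnot(inherits(a, "strategy_outcome"), inherits(b, "strategy_outcome"))
  dc <- a$cost - b$cost
  de <- a$qaly - b$qaly
  list(delta_cost = dc, delta_qaly = de,
       icer = if (de != 0) dc / de else NA_real_,
       icer_defined = de != 0)
}

#' Cost-effectiveness frontier and dominance classification
#'
#' Classifies each strategy as on the frontier, strictly dominated
#' (costlier and no more effective than some alternative; equal-QALY ties
#' keep the cheaper strategy) or extended dominated (removed when frontier
#' ICERs are non-monotone). The remaining frontier, sorted by QALY, has
#' strictly increasing incremental ICERs.
#'
#' @param outcomes A list of two or more [strategy_outcome()] objects.
#' @return A data frame with one row per strategy: `strategy`, `cost`,
#'   `qaly`, `dominance` (`"frontier"`, `"dominated"`,
#'   `"extended_dominated"`) and `icer` (incremental ICER vs the previous
#'   frontier strategy; `NA` for the cheapest frontier strategy and for
#'   non-frontier strategies). Row order follows the input.
#' @export
frontier <- function(outcomes) {
  stopifnot(is.list(outcomes), length(outcomes) >= 2L,
            all(vapply(outcomes, inherits, logical(1), "strategy_outcome")))
  n <- length(outcomes)
  cost <- vapply(outcomes, `[[`, numeric(1), "cost")
  qaly <- vapply(outcomes, `[[`, numeric(1), "qaly")
  lab <- vapply(outcomes, `[[`, character(1), "strategy")
  dominance <- rep("frontier", n)
  # strict dominance (ties on QALY keep the cheaper strategy)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if ((cost[i] > cost[j] && qaly[i] <= qaly[j]) ||
        (cost[i] == cost[j] && qaly[i] < qaly[j]))
      dominance[i] <- "dominated"
  }
  # extended dominance: iterate until frontier ICERs increase along QALYs
  repeat {
    idx <- which(dominance == "frontier")
    ord <- idx[order(qaly[idx], cost[idx])]
    if (length(ord) < 3L) break
    icers <- diff(cost[ord]) / diff(qaly[ord])
    bad <- which(diff(icers) <= 0)
    if (length(bad) == 0L) break
    dominance[ord[bad[1L] + 1L]] <- "extended_dominated"
  }
  icer_col <- rep(NA_real_, n)
  idx <- which(dominance == "frontier")
  ord <- idx[order(qaly[idx], cost[idx])]
  if (length(ord) >= 2L)
    icer_col[ord[-1L]] <- diff(cost[ord]) / diff(qaly[ord])
  data.frame(strategy = lab, cost = cost, qaly = qaly,
             dominance = dominance, icer = icer_col)
}

#' Net health benefit
#'
#' \eqn{NHB = \Delta E - \Delta C / WTP}, in QALYs. Positive exactly when
#' the ICER is below the willingness-to-pay threshold (for
#' \eqn{\Delta E > 0}).
#'
#' @param delta_cost Incremental cost in dollars.
#' @param delta_qaly Incremental effectiveness in QALYs.
#' @param wtp Willingness to pay per QALY, `> 0`.
#' @return Net health benefit in QALYs.
#' @export
net_health_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp <= 0)) stop("`wtp` must be positive")
  delta_qaly - delta_cost / wtp
}

#' Net monetary benefit
#'
#' \eqn{NMB = E \cdot WTP - C}, in dollars; used for the acceptability-curve
#' argmax.
#'
#' @param cost Total cost in dollars.
#' @param qaly Total QALYs.
#' @param wtp Willingness to pay per QALY, `> 0`.
#' @return Net monetary benefit in dollars.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp <= 0)) stop("`wtp` must be positive")
  qaly * wtp - cost
}
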