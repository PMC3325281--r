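#' Health-state utility table
#'
#' State utilities (EQ-5D-style weights in `[0, 1]`) with plausible ranges,
#' plus the monthly progressed-state decrement. Defaults come from the
#' shipped utility fixture; any state can be overridden.
#'
#' @param ... Named overrides: a `list(mean, low, high)` or a single number.
#' @param progression_decrement Utility lost per month spent in the
#'   progressed state (default from the fixture, 0.02/month).
#' @param file Optional YAML file instead of the shipped fixture.
#' @return An object of class `utility_table`.
#' @export
utility_table <- function(..., progression_decrement = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "utilities.yaml", package = "gbmcea")
  raw <- yaml::read_yaml(file)
  states <- lapply(raw$states, function(x) x[c("mean", "low", "high")])
  over <- list(...)
  for (nm in names(over)) {
    x <- over[[nm]]
    if (is.numeric(x) && length(x) == 1L) x <- list(mean = x, low = x, high = x)
    states[[nm]] <- as.list(x)[c("mean", "low", "high")]
  }
  for (nm in names(states)) {
    st <- states[[nm]]
    if (st$mean < 0 || st$mean > 1 || st$high > 1 || st$low < 0)
      stop("utilities must lie in [0, 1]: ", nm)
    if (!(st$low <= st$mean && st$mean <= st$high))
      stop("require low <= mean <= high for utility ", nm)
  }
  if (is.null(progression_decrement))
    progression_decrement <- raw$progression_decrement_per_month
  structure(c(states, list(progression_decrement = progression_decrement)),
            class = "utility_table")
}

#' Disease-free utility by treatment phase
#'
#' Maps a strategy and cycle index to the disease-free utility in force:
#' the combined radiotherapy(+chemotherapy) value during the concomitant
#' phase (cycles 0-1), the adjuvant-chemotherapy value during adjuvant
#' cycles (cycles 3-8 for the TMZ strategy; every cycle from 2 onwards for
#' the NT strategy, whose ACNU continues until progression), and the
#' untreated disease-free value otherwise.
#'
#' @param strategy `"RT"`, `"RT+NT"` or `"RT+TMZ"`.
#' @param cycle Cycle index, `>= 0`.
#' @param table A [utility_table()].
#' @param schedule Optional [strategy_schedule()] whose phase boundaries
#'   override the defaults.
#' @return A utility weight.
#' @export
pf_phase_utility <- function(strategy, cycle, table, schedule = NULL) {
  stopifnot(inherits(table, "utility_table"))
  strategy <- match.arg(strategy, c("RT", "RT+NT", "RT+TMZ"))
  conc_end <- if (is.null(schedule)) 1L
              else length(schedule$rt_fractions_by_cycle) - 1L
  adj_cycles <- if (is.null(schedule)) 3:8 else schedule$adjuvant_cycles
  if (cycle <= conc_end)
    return(switch(strategy, "RT" = table$pf_rt$mean,
                  "RT+TMZ" = table$pf_rt_tmz$mean,
                  "RT+NT" = table$pf_rt_nt$mean))
  if (strategy == "RT+TMZ" && cycle %in% adj_cycles)
    return(table$pf_tmz_adjuvant$mean)
  if (strategy == "RT+NT" && cycle > conc_end)
    return(table$pf_nt_adjuvant$mean)
  table$pf_no_treatment$mean
}

#' Expected utility of the progressed state at a cycle
#'
#' Entry-cohort (tunnel) average: members who entered progression at cycle
#' `s` carry utility `max(0, progressed - decrement * (cycle - s))`; entry
#' cohorts are weighted by their entrant mass under proportional depletion
#' by subsequent deaths. Returns 0 when nobody is progressed (by
#' convention).
#'
#' @param trace A [run_cohort()] trace.
#' @param cycle Cycle index.
#' @param table A [utility_table()].
#' @return A utility weight in `[0, 1]`.
#' @export
progressed_expected_utility <- function(trace, cycle, table) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(table, "utility_table"))
  if (trace$prog[cycle + 1L] <= 0) return(0)
  w <- prog_entry_weights(trace, cycle)
  if (sum(w) == 0) return(0)
  s <- seq_along(w) - 1L
  sum(w * pmax(0, table$progressed$mean -
                 table$progression_decrement * (cycle - s)))
}

#' Total quality-adjusted life-years over the horizon
#'
#' \deqn{\sum_{t=0}^{H-1} \left[ pf(t)\,u_{PF}(t) + prog(t)\,u_{prog}(t)
#'   \right] / 12,}
#' with start-of-cycle occupancies, the phase-dependent disease-free utility
#' and the entry-cohort progressed utility. Health outcomes are not
#' discounted by default.
#'
#' @inheritParams progressed_expected_utility
#' @param strategy `"RT"`, `"RT+NT"` or `"RT+TMZ"`.
#' @param schedule Optional [strategy_schedule()] for phase boundaries.
#' @param discount_rate Annual discount rate (default 0).
#' @return QALYs per starting cohort member.
#' @export
total_qaly <- function(trace, strategy, table, schedule = NULL,
                       discount_rate = 0) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(table, "utility_table"))
  horizon <- max(trace$cycle)
  tot <- 0
  for (cyc in 0:(horizon - 1L)) {
    u <- trace$pf[cyc + 1L] * pf_phase_utility(strategy, cyc, table, schedule) +
      trace$prog[cyc + 1L] * progressed_expected_utility(trace, cyc, table)
    tot <- tot + u * (1 + discount_rate)^(-cyc / 12)
  }
  tot / 12
}
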