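#' Build the three-state monthly cohort trace
#'
#' Partitioned-survival occupancy: the disease-free fraction is the PFS
#' survivor function, the dead fraction is one minus the OS survivor
#' function, and the progressed fraction is the difference
#' \eqn{S_{OS}(t) - S_{PFS}(t)} (clamped at zero). Entrants to progression
#' in cycle \eqn{t} are `new_prog(t) = max(0, pf(t-1) - pf(t))`, i.e. all
#' leavers of the disease-free state are counted as progressors; the small
#' direct disease-free-to-death flow is absorbed into this convention (it
#' only affects the progressed-state utility tunnel).
#'
#' If the PFS curve rises above the OS curve by more than `cross_tol`
#' anywhere (possible with imputed subgroup parameters) a warning is issued
#' and the progressed occupancy is clamped at zero.
#'
#' @param pfs,os [weibull_params()] for the arm's PFS and OS endpoints.
#' @param horizon Number of monthly cycles, `>= 1` (default 60, i.e. 5 years).
#' @param cross_tol Tolerance for PFS/OS curve crossing before warning
#'   (default 0.02).
#' @return A `cohort_trace`: a data frame with columns `cycle` (0..horizon),
#'   `pf`, `prog`, `dead` (occupancy fractions summing to 1) and `new_prog`.
#' @examples
#' tr <- run_cohort(weibull_params(1.3, log(2) / 4.7^1.3),
#'                  weibull_params(1.3, log(2) / 11.7^1.3))
#' head(tr)
#' @export
run_cohort <- function(pfs, os, horizon = 60, cross_tol = 0.02) {
  stopifnot(inherits(pfs, "weibull_params"), inherits(os, "weibull_params"))
  if (horizon < 1) stop("`horizon` must be at least 1")
  t <- 0:horizon
  s_pfs <- weibull_survival(pfs, t)
  s_os <- weibull_survival(os, t)
  if (any(s_pfs - s_os > cross_tol))
    warning(sprintf("PFS exceeds OS by up to %.3g; progressed occupancy clamped at 0",
                    max(s_pfs - s_os)))
  pf <- pmin(s_pfs, s_os)  # keep conservation exact under crossing
  dead <- 1 - s_os
  prog <- pmax(0, s_os - s_pfs)
  new_prog <- c(0, pmax(0, -diff(pf)))
  out <- data.frame(cycle = t, pf = pf, prog = prog, dead = dead,
                    new_prog = new_prog)
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Median survival time read off a cohort trace
#'
#' Linear interpolation of the first crossing of 0.5 by the relevant
#' survivor curve: `pf` for PFS, `pf + prog` for OS.
#'
#' @param trace A [run_cohort()] trace.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return Median in months.
#' @export
model_median_from_trace <- function(trace, endpoint = c("OS", "PFS")) {
  stopifnot(inherits(trace, "cohort_trace"))
  endpoint <- match.arg(endpoint)
  s <- if (endpoint == "PFS") trace$pf else trace$pf + trace$prog
  below <- which(s <= 0.5)
  if (length(below) == 0L)
    stop(sprintf("%s survival never falls below 0.5 within the horizon; median not reached",
                 endpoint))
  i <- below[1L]
  if (i == 1L) return(trace$cycle[1L])
  t0 <- trace$cycle[i - 1L]; t1 <- trace$cycle[i]
  s0 <- s[i - 1L]; s1 <- s[i]
  t0 + (s0 - 0.5) / (s0 - s1) * (t1 - t0)
}

#' Trial median with 95% confidence interval
#'
#' @param cohort,arm,endpoint Identifying labels.
#' @param median,ci_low,ci_high Months; must satisfy
#'   `ci_low <= median <= ci_high`.
#' @return An object of class `trial_median`.
#' @export
trial_median <- function(cohort, arm, endpoint, median, ci_low, ci_high) {
  if (!(ci_low <= median && median <= ci_high))
    stop("require ci_low <= median <= ci_high")
  structure(list(cohort = cohort, arm = arm, endpoint = endpoint,
                 median = median, ci_low = ci_low, ci_high = ci_high),
            class = "trial_median")
}

#' Validate a model median against a trial confidence interval
#'
#' The model passes when its median lies inside the trial's 95% CI
#' (inclusive bounds). The margin is the signed distance to the nearest
#' bound: negative inside the interval, positive outside.
#'
#' @param model_median Model-estimated median in months.
#' @param trial A [trial_median()] object.
#' @return A list with `pass` (logical) and `margin` (months).
#' @export
validate_against_trial <- function(model_median, trial) {
  stopifnot(inherits(trial, "trial_median"))
  pass <- trial$ci_low <= model_median && model_median <= trial$ci_high
  margin <- if (pass)
    -min(model_median - trial$ci_low, trial$ci_high - model_median)
  else if (model_median > trial$ci_high) model_median - trial$ci_high
  else trial$ci_low - model_median
  list(pass = pass, margin = margin)
}

# Entry-cohort (tunnel) weights over progression entrants at a given cycle:
# the share of current progressed members that entered at each cycle s <= cycle,
# under proportional depletion by deaths. Returns a vector over s = 0..cycle
# (zeros when nobody has progressed yet).
prog_entry_weights <- function(trace, cycle) {
  w <- trace$new_prog[seq_len(cycle + 1L)]
  tot <- sum(w)
  if (tot <= 0) return(numeric(cycle + 1L))
  w / tot
}
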