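# Shared fixtures and independent oracles used across test files.

# Config built once; tests treat it as read-only.
fixture_config <- function() {
  if (is.null(.fixture_env$cfg)) .fixture_env$cfg <- default_config()
  .fixture_env$cfg
}
.fixture_env <- new.env(parent = emptyenv())

# Independent brute-force dominance oracle: strict dominance by pairwise
# comparison; extended dominance by checking, for each remaining strategy,
# whether a convex combination of two others delivers at least its QALY at
# lower cost (the textbook definition, checked on a fine mixture grid).
oracle_dominance <- function(cost, qaly) {
  n <- length(cost)
  cls <- rep("frontier", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if ((cost[i] > cost[j] && qaly[i] <= qaly[j]) ||
        (cost[i] == cost[j] && qaly[i] < qaly[j]))
      cls[i] <- "dominated"
  }
  for (i in which(cls == "frontier")) {
    others <- setdiff(which(cls != "dominated"), i)
    for (j in others) for (k in others) {
      if (j >= k) next
      for (w in seq(0, 1, by = 0.001)) {
        qm <- w * qaly[j] + (1 - w) * qaly[k]
        cm <- w * cost[j] + (1 - w) * cost[k]
        if (qm >= qaly[i] - 1e-12 && cm < cost[i] - 1e-9) {
          cls[i] <- "extended_dominated"
          break
        }
      }
      if (cls[i] == "extended_dominated") break
    }
  }
  cls
}

# Hand-rolled product-limit estimator (independent of survival::survfit).
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (tt in unique(time[event == 1])) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
    out_t <- c(out_t, tt); out_s <- c(out_s, s)
  }
  data.frame(time = out_t, surv = out_s)
}

# Minimal cohort_trace construction for targeted costing/utility tests.
make_trace <- function(pf, prog, dead, new_prog = NULL) {
  if (is.null(new_prog)) new_prog <- c(0, pmax(0, -diff(pf)))
  out <- data.frame(cycle = seq_along(pf) - 1L, pf = pf, prog = prog,
                    dead = dead, new_prog = new_prog)
  class(out) <- c("cohort_trace", "data.frame")
  out
}
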