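#' Distribution descriptors for probabilistic sensitivity analysis
#'
#' Assigns the standard distribution families to every uncertain input:
#' lognormal for costs, beta for utilities, probabilities and proportions,
#' and bivariate normal for each Weibull (shape, scale) pair. Ranges
#' `(low, high)` are read as central 95% intervals:
#' * lognormal: `sdlog = (ln high - ln low) / (2 x 1.96)` with `meanlog`
#'   adjusted so the distribution mean equals the item mean
#'   (`meanlog = ln mean - sdlog^2 / 2`);
#' * beta: method of moments with `sd = (high - low) / (2 x 1.96)`;
#' * Weibull pairs: mean vector `(shape, scale)` and covariance from the
#'   standard errors and correlation.
#' Items with `low == high == mean` become degenerate (the draw is the
#' mean); `degenerate = TRUE` collapses every descriptor, so the PSA
#' reproduces the base case exactly.
#'
#' @param config A [default_config()]-style configuration.
#' @param degenerate Collapse all distributions onto their means.
#' @return An object of class `psa_spec`.
#' @export
build_distributions <- function(config, degenerate = FALSE) {
  stopifnot(inherits(config, "gbm_config"))
  deg <- function(m) list(kind = "degenerate", mean = m)
  lognorm <- function(it) {
    if (degenerate || it$low == it$high) return(deg(it$mean))
    if (it$high <= it$low) stop("degenerate range: high <= low")
    if (it$mean <= 0 || it$low <= 0) stop("lognormal needs positive values")
    sdlog <- (log(it$high) - log(it$low)) / (2 * 1.96)
    list(kind = "lognormal", mean = it$mean,
         meanlog = log(it$mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  beta_d <- function(it) {
    if (degenerate || it$low == it$high) return(deg(it$mean))
    if (it$high <= it$low) stop("degenerate range: high <= low")
    if (it$mean <= 0 || it$mean >= 1)
      stop("beta moments outside (0,1) support")
    v <- ((it$high - it$low) / (2 * 1.96))^2
    common <- it$mean * (1 - it$mean) / v - 1
    if (common <= 0) stop("beta variance too large for mean ", it$mean)
    list(kind = "beta", mean = it$mean,
         alpha = it$mean * common, beta = (1 - it$mean) * common)
  }
  wb <- function(row) {
    mu <- c(row$shape, row$scale)
    if (degenerate || (row$se_shape == 0 && row$se_scale == 0))
      return(list(kind = "degenerate_pair", mean = mu))
    Sigma <- matrix(c(row$se_shape^2,
                      row$corr * row$se_shape * row$se_scale,
                      row$corr * row$se_shape * row$se_scale,
                      row$se_scale^2), 2, 2)
    list(kind = "bvnormal", mean = mu, sigma = Sigma)
  }
  p <- config$params
  weib <- lapply(seq_len(nrow(p)), function(i) wb(p[i, ]))
  names(weib) <- paste(p$cohort, p$arm, p$endpoint, sep = ".")
  structure(list(
    costs = lapply(config$costs, lognorm),
    utilities = lapply(config$utilities[setdiff(names(config$utilities),
                                                "progression_decrement")],
                       beta_d),
    sae_probs = lapply(config$sae_probs, beta_d),
    second_line_mix = lapply(config$second_line_mix, beta_d),
    hr_nt = lapply(config$hr_nt, lognorm),
    weibull = weib), class = "psa_spec")
}

draw_scalar <- function(d) {
  switch(d$kind,
         degenerate = d$mean,
         lognormal = stats::rlnorm(1, d$meanlog, d$sdlog),
         beta = stats::rbeta(1, d$alpha, d$beta),
         stop("unknown descriptor kind ", d$kind))
}

# Draw a (shape, scale) pair; invalid (<= 0) draws are resampled and counted
# in the environment `counter` (field `resampled`).
draw_pair <- function(d, counter) {
  if (d$kind == "degenerate_pair") return(d$mean)
  repeat {
    x <- MASS::mvrnorm(1, d$mean, d$sigma)
    if (all(x > 0)) return(x)
    counter$resampled <- counter$resampled + 1L
  }
}

# One sampled configuration (deterministic given the RNG state).
draw_config <- function(config, spec, counter) {
  cfg <- config
  for (nm in names(spec$costs))
    cfg$costs[[nm]]$mean <- draw_scalar(spec$costs[[nm]])
  for (nm in names(spec$utilities))
    cfg$utilities[[nm]]$mean <- draw_scalar(spec$utilities[[nm]])
  for (nm in names(spec$sae_probs))
    cfg$sae_probs[[nm]]$mean <- draw_scalar(spec$sae_probs[[nm]])
  mix <- vapply(spec$second_line_mix, draw_scalar, numeric(1))
  mix <- mix / sum(mix)  # proportions renormalized to sum to 1
  for (nm in names(mix)) cfg$second_line_mix[[nm]]$mean <- mix[[nm]]
  for (nm in names(spec$hr_nt))
    cfg$hr_nt[[nm]]$mean <- draw_scalar(spec$hr_nt[[nm]])
  for (i in seq_len(nrow(cfg$params))) {
    key <- paste(cfg$params$cohort[i], cfg$params$arm[i],
                 cfg$params$endpoint[i], sep = ".")
    pair <- draw_pair(spec$weibull[[key]], counter)
    cfg$params$shape[i] <- pair[1]
    cfg$params$scale[i] <- pair[2]
  }
  cfg
}

#' Probabilistic sensitivity analysis (Monte-Carlo)
#'
#' For each draw, samples every uncertain parameter from its assigned
#' distribution, rebuilds the survival models (including subgroup PFS
#' imputation and the nitrosourea hazard-ratio scaling), reruns the trace,
#' costing and QALY accrual for all three strategies, and records the
#' per-draw totals. Fixed seed implies identical output. Draws producing
#' invalid (non-positive) Weibull parameters are resampled; the count is
#' available as `attr(x, "resampled")`.
#'
#' @inheritParams build_distributions
#' @param cohort Cohort to analyse (default `"overall"`).
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param spec Optional pre-built [build_distributions()] spec.
#' @return A `psa_draws` data frame: `draw`, `strategy`, `cost`, `qaly`.
#' @export
run_psa <- function(config = default_config(), cohort = "overall",
                    n_draws = 1000, seed = 1, spec = NULL) {
  stopifnot(inherits(config, "gbm_config"), n_draws >= 1)
  if (is.null(spec)) spec <- build_distributions(config)
  set.seed(seed)
  counter <- new.env(parent = emptyenv())
  counter$resampled <- 0L
  strategies <- gbm_strategies()
  cost <- qaly <- matrix(NA_real_, n_draws, length(strategies),
                         dimnames = list(NULL, strategies))
  crossed <- 0L
  for (d in seq_len(n_draws)) {
    cfg <- draw_config(config, spec, counter)
    # independently drawn PFS/OS pairs may cross; the trace clamps and warns,
    # which is counted here rather than emitted once per draw
    withCallingHandlers({
      models <- cohort_models(cfg, cohort)
      for (s in strategies) {
        ev <- evaluate_strategy(cfg, cohort, s, models)
        cost[d, s] <- ev$outcome$cost
        qaly[d, s] <- ev$outcome$qaly
      }
    }, warning = function(w) {
      if (grepl("PFS exceeds OS", conditionMessage(w))) {
        crossed <<- crossed + 1L
        invokeRestart("muffleWarning")
      }
    })
  }
  out <- data.frame(draw = rep(seq_len(n_draws), each = length(strategies)),
                    strategy = rep(strategies, n_draws),
                    cost = as.vector(t(cost)), qaly = as.vector(t(qaly)))
  class(out) <- c("psa_draws", "data.frame")
  attr(out, "resampled") <- counter$resampled
  attr(out, "crossed") <- crossed
  attr(out, "cohort") <- cohort
  out
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability (over PSA draws) that
#' each strategy has the maximal net monetary benefit
#' \eqn{E \cdot WTP - C}. Ties split equally, so probabilities across
#' strategies sum to 1 at every threshold.
#'
#' @param draws A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay values, `> 0` (default 120 steps of
#'   $1,000 up to $120,000, covering both reference thresholds).
#' @return A data frame `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(1000, 120000, by = 1000)) {
  stopifnot(inherits(draws, "psa_draws"))
  if (any(wtp_grid <= 0)) stop("`wtp` values must be positive")
  strategies <- unique(draws$strategy)
  cost <- matrix(draws$cost, ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(draws$qaly, ncol = length(strategies), byrow = TRUE)
  rows <- lapply(wtp_grid, function(w) {
    nmb <- qaly * w - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)   # ties split equally
    data.frame(wtp = w, strategy = strategies,
               probability = colMeans(share))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 95% confidence ellipse on the cost-effectiveness plane
#'
#' Bivariate-normal 95% coverage ellipse of the incremental
#' (\eqn{\Delta E}, \eqn{\Delta C}) cloud for a strategy pair, from the
#' sample mean and covariance with the chi-square (2 df) 0.95 radius.
#'
#' @param draws A [run_psa()] result with at least 3 draws.
#' @param pair Character vector `c(a, b)`: increments are a minus b
#'   (default TMZ vs RT).
#' @return A list: `center` (\eqn{\Delta E}, \eqn{\Delta C}), `cov`,
#'   `axes` (semi-axis lengths), `angle` (radians, major axis vs the
#'   \eqn{\Delta E} axis), `radius2` (the chi-square quantile).
#' @export
ci_ellipse <- function(draws, pair = c("RT+TMZ", "RT")) {
  stopifnot(inherits(draws, "psa_draws"), length(pair) == 2L)
  a <- draws[draws$strategy == pair[1L], ]
  b <- draws[draws$strategy == pair[2L], ]
  if (nrow(a) < 3L) stop("need at least 3 draws")
  de <- a$qaly - b$qaly
  dc <- a$cost - b$cost
  xy <- cbind(delta_qaly = de, delta_cost = dc)
  S <- stats::cov(xy)
  if (det(S) <= .Machine$double.eps * max(1, prod(diag(S))))
    stop("singular covariance: draws are degenerate")
  eg <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(0.95, df = 2)
  list(center = colMeans(xy), cov = S,
       axes = sqrt(eg$values * r2),
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       radius2 = r2)
}

# settable parameter ids for one-way analysis
modify_config <- function(config, parameter, value) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1L]]
  cfg <- config
  if (parts[1L] == "cost" && length(parts) == 2L &&
      parts[2L] %in% names(cfg$costs)) {
    cfg$costs[[parts[2L]]]$mean <- value
  } else if (parts[1L] == "utility" && length(parts) == 2L &&
             parts[2L] %in% names(cfg$utilities)) {
    cfg$utilities[[parts[2L]]]$mean <- value
  } else if (parts[1L] == "bsa") {
    cfg$profile <- patient_profile(cfg$profile$weight, cfg$profile$height,
                                   bsa = value)
  } else if (parts[1L] == "hr_nt" && length(parts) == 2L &&
             parts[2L] %in% names(cfg$hr_nt)) {
    cfg$hr_nt[[parts[2L]]]$mean <- value
  } else if (parts[1L] == "sae" && length(parts) == 2L &&
             parts[2L] %in% names(cfg$sae_probs)) {
    cfg$sae_probs[[parts[2L]]]$mean <- value
  } else if (parts[1L] == "weibull" && length(parts) == 5L) {
    i <- which(cfg$params$cohort == parts[2L] & cfg$params$arm == parts[3L] &
                 cfg$params$endpoint == parts[4L])
    if (length(i) != 1L || !parts[5L] %in% c("shape", "scale"))
      stop("unknown parameter id '", parameter, "'")
    cfg$params[[parts[5L]]][i] <- value
  } else {
    stop("unknown parameter id '", parameter, "'")
  }
  cfg
}

#' One-way sensitivity analysis of one parameter
#'
#' Reruns the full deterministic model with the parameter set to its low
#' and high value (all else at base case) and reports the net health
#' benefit of the comparison (TMZ vs RT by default) at both ends.
#'
#' @inheritParams build_distributions
#' @param parameter Parameter id, e.g. `"cost.tmz_100mg"`,
#'   `"utility.pf_tmz_adjuvant"`, `"bsa"`, `"hr_nt.os"`,
#'   `"sae.hematologic"`, `"weibull.overall.RT.OS.scale"`.
#' @param low,high Range ends (`low <= high`).
#' @param wtp Willingness to pay per QALY (default the $11,034 threshold).
#' @param cohort Cohort label.
#' @param comparison Strategy pair `c(a, b)`.
#' @return A list: `nhb_low`, `nhb_high`, `width`, `nhb_base`.
#' @export
one_way <- function(config = default_config(), parameter, low, high,
                    wtp = NULL, cohort = "overall",
                    comparison = c("RT+TMZ", "RT")) {
  if (low > high) stop("`low` must not exceed `high`")
  if (is.null(wtp)) wtp <- config$settings$wtp_china
  nhb_at <- function(cfg) {
    models <- cohort_models(cfg, cohort)
    a <- evaluate_strategy(cfg, cohort, comparison[1L], models)$outcome
    b <- evaluate_strategy(cfg, cohort, comparison[2L], models)$outcome
    inc <- incremental(a, b)
    net_health_benefit(inc$delta_cost, inc$delta_qaly, wtp)
  }
  nhb_low <- nhb_at(modify_config(config, parameter, low))
  nhb_high <- if (high == low) nhb_low
              else nhb_at(modify_config(config, parameter, high))
  list(nhb_low = nhb_low, nhb_high = nhb_high,
       width = abs(nhb_high - nhb_low), nhb_base = nhb_at(config))
}

# default tornado parameter set with ranges from the configuration
tornado_parameters <- function(config) {
  rows <- list()
  add <- function(id, low, high)
    rows[[length(rows) + 1L]] <<- data.frame(parameter = id, low = low,
                                             high = high)
  for (nm in names(config$costs))
    add(paste0("cost.", nm), config$costs[[nm]]$low, config$costs[[nm]]$high)
  for (nm in setdiff(names(config$utilities), "progression_decrement"))
    add(paste0("utility.", nm), config$utilities[[nm]]$low,
        config$utilities[[nm]]$high)
  add("bsa", config$settings$bsa_range[1L], config$settings$bsa_range[2L])
  for (nm in names(config$hr_nt))
    add(paste0("hr_nt.", nm), config$hr_nt[[nm]]$low, config$hr_nt[[nm]]$high)
  for (nm in names(config$sae_probs))
    add(paste0("sae.", nm), config$sae_probs[[nm]]$low,
        config$sae_probs[[nm]]$high)
  p <- config$params
  for (i in which(p$cohort == "overall")) {
    id <- paste("weibull", p$cohort[i], p$arm[i], p$endpoint[i], "scale",
                sep = ".")
    add(id, max(1e-8, p$scale[i] - 1.96 * p$se_scale[i]),
        p$scale[i] + 1.96 * p$se_scale[i])
  }
  do.call(rbind, rows)
}

#' Tornado (one-way sensitivity) report
#'
#' Runs [one_way()] for every parameter with a configured range and sorts
#' by bar width (descending).
#'
#' @inheritParams one_way
#' @param parameters Optional data frame `parameter`, `low`, `high`;
#'   defaults to every cost, utility, BSA, hazard-ratio, SAE-probability
#'   and overall-cohort Weibull-scale range in the configuration.
#' @return A data frame `parameter`, `low`, `high`, `nhb_low`, `nhb_high`,
#'   `width`, `rank`.
#' @export
tornado <- function(config = default_config(), wtp = NULL, cohort = "overall",
                    comparison = c("RT+TMZ", "RT"), parameters = NULL) {
  if (is.null(parameters)) parameters <- tornado_parameters(config)
  res <- lapply(seq_len(nrow(parameters)), function(i) {
    r <- parameters[i, ]
    ow <- one_way(config, r$parameter, r$low, r$high, wtp = wtp,
                  cohort = cohort, comparison = comparison)
    data.frame(parameter = r$parameter, low = r$low, high = r$high,
               nhb_low = ow$nhb_low, nhb_high = ow$nhb_high,
               width = ow$width)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$width), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
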