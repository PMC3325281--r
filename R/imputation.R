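#' Cycle-wise PFS/OS hazard-rate ratio series
#'
#' Evaluates \eqn{r(t) = h_{PFS}(t) / h_{OS}(t)} on the integer-month grid
#' \eqn{t = 1, \dots, H}. With a shared shape \eqn{k} the ratio is the
#' constant \eqn{\lambda_{PFS}/\lambda_{OS}}; with distinct shapes it varies
#' as a power of \eqn{t}. The grid starts at 1 month to avoid the
#' \eqn{t^{k-1}} singularity at the origin (cycle-end evaluation; see the
#' methods vignette).
#'
#' @param pfs,os [weibull_params()] for the PFS and OS endpoints of the same
#'   arm and cohort.
#' @param horizon_cycles Number of monthly cycles, `>= 2`.
#' @return An object of class `hazard_series` with fields `cycle_times`
#'   (months) and `values` (dimensionless ratios).
#' @export
hazard_ratio_series <- function(pfs, os, horizon_cycles = 60) {
  stopifnot(inherits(pfs, "weibull_params"), inherits(os, "weibull_params"))
  if (horizon_cycles < 2) stop("`horizon_cycles` must be at least 2")
  t <- seq_len(horizon_cycles)
  h_os <- weibull_hazard(os, t)
  if (any(h_os <= 0)) stop("OS hazard is zero on the grid; invalid inputs")
  structure(list(cycle_times = t, values = weibull_hazard(pfs, t) / h_os),
            class = "hazard_series")
}

# Least-squares Weibull fit to a positive hazard series in log space:
# ln h(t) = ln(scale * shape) + (shape - 1) ln t. Exact when the series is a
# true Weibull hazard. Returns weibull_params with regression-based SEs
# (delta method), flagged approximate via attribute.
fit_weibull_hazard_series <- function(times, hazards) {
  if (any(hazards <= 0)) stop("non-positive hazards; invalid inputs")
  if (length(times) < 3L) stop("need at least 3 grid points")
  x <- log(times)
  y <- log(hazards)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  shape <- unname(co["x"]) + 1
  if (shape <= 0) stop("fitted shape is non-positive")
  scale <- exp(unname(co["(Intercept)"])) / shape
  # a true-Weibull series fits exactly; suppress the perfect-fit warning
  vc <- suppressWarnings(stats::vcov(fit))
  # d(scale)/d(intercept) = scale; d(scale)/d(slope) = -scale/shape
  g <- c(scale, -scale / shape)
  se_scale <- sqrt(max(0, t(g) %*% vc %*% g))
  se_shape <- sqrt(vc[2, 2])
  cv <- g[1] * vc[1, 2] + g[2] * vc[2, 2]
  corr <- if (se_scale > 0 && se_shape > 0) cv / (se_scale * se_shape) else 0
  out <- weibull_params(shape = shape, scale = scale,
                        se_shape = se_shape, se_scale = se_scale,
                        corr = max(-1, min(1, corr)))
  attr(out, "se_method") <- "log-hazard regression (approximate)"
  out
}

#' Impute missing subgroup PFS Weibull parameters
#'
#' Three-step imputation of a subgroup's progression-free survival when only
#' its overall-survival model is available, under the assumption that the
#' cycle-wise PFS/OS hazard-rate ratio of the overall cohort carries over to
#' the subgroup:
#' 1. compute \eqn{r(t) = h_{PFS,ov}(t)/h_{OS,ov}(t)} on the monthly grid;
#' 2. form the subgroup PFS hazard series \eqn{r(t) \, h_{OS,sub}(t)};
#' 3. refit a Weibull hazard to that series by least squares on
#'    \eqn{\ln h(t)}.
#'
#' When all three inputs share a shape the result is available in closed
#' form (`scale = scale_sub_os * scale_ov_pfs / scale_ov_os`, same shape)
#' and the regression recovers it exactly.
#'
#' @param overall_pfs,overall_os Overall-cohort PFS and OS models.
#' @param subgroup_os Subgroup OS model.
#' @param horizon_cycles Grid length in months, `>= 3` (default 60).
#' @return A [weibull_params()] object with attribute `imputed = TRUE`.
#' @export
impute_subgroup_pfs <- function(overall_pfs, overall_os, subgroup_os,
                                horizon_cycles = 60) {
  stopifnot(inherits(subgroup_os, "weibull_params"))
  if (horizon_cycles < 3) stop("`horizon_cycles` must be at least 3")
  r <- hazard_ratio_series(overall_pfs, overall_os, horizon_cycles)
  h_sub_pfs <- r$values * weibull_hazard(subgroup_os, r$cycle_times)
  out <- fit_weibull_hazard_series(r$cycle_times, h_sub_pfs)
  attr(out, "imputed") <- TRUE
  out
}
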