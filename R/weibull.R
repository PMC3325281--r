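#' Weibull survival parameters
#'
#' Container for a two-parameter Weibull survival model in the *rate*
#' parameterization \eqn{S(t) = \exp(-\lambda t^k)}, with \eqn{k} the shape
#' and \eqn{\lambda} the scale (rate). Time is measured in months throughout.
#' Under this parameterization the hazard is \eqn{h(t) = \lambda k t^{k-1}},
#' so multiplying the scale by a hazard ratio multiplies the hazard by the
#' same factor at every time -- the proportional-hazards property used for
#' the indirect comparison of treatment arms.
#'
#' @param shape Positive dimensionless shape parameter \eqn{k}.
#' @param scale Positive scale parameter. Interpreted as the rate
#'   \eqn{\lambda} when `parameterization = "rate"` (the default). When
#'   `parameterization = "characteristic_life"` the value is the
#'   characteristic life \eqn{b} of \eqn{S(t)=\exp(-(t/b)^k)} and is
#'   converted internally to \eqn{\lambda = b^{-k}} (standard errors are
#'   converted by the delta method).
#' @param se_shape,se_scale Non-negative standard errors of the estimates
#'   (default 0).
#' @param corr Correlation between the shape and scale estimates, in
#'   \eqn{[-1, 1]} (default 0).
#' @param parameterization Either `"rate"` or `"characteristic_life"`.
#'
#' @return An object of class `weibull_params`.
#' @examples
#' p <- weibull_params(shape = 1.3, scale = 0.05)
#' weibull_survival(p, 12)
#' weibull_median(p)
#' @export
weibull_params <- function(shape, scale, se_shape = 0, se_scale = 0, corr = 0,
                           parameterization = c("rate", "characteristic_life")) {
  parameterization <- match.arg(parameterization)
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (shape <= 0) stop("`shape` must be positive")
  if (scale <= 0) stop("`scale` must be positive")
  if (se_shape < 0 || se_scale < 0) stop("standard errors must be non-negative")
  if (abs(corr) > 1) stop("`corr` must lie in [-1, 1]")
  if (parameterization == "characteristic_life") {
    # lambda = b^(-k); delta method: d lambda / d b = -k b^(-k-1)
    b <- scale
    scale <- b^(-shape)
    se_scale <- se_scale * shape * b^(-shape - 1)
  }
  structure(list(shape = shape, scale = scale,
                 se_shape = se_shape, se_scale = se_scale, corr = corr),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull (rate parameterization): shape = %.4g (SE %.3g), scale = %.4g (SE %.3g)\n",
              x$shape, x$se_shape, x$scale, x$se_scale))
  cat(sprintf("  median = %.2f months\n", weibull_median(x)))
  invisible(x)
}

#' Kaplan-Meier curve coordinates
#'
#' @param times Strictly increasing event times in months, all `>= 0`.
#' @param surv Survival probabilities at `times`, non-increasing, in `(0, 1]`.
#' @param n_risk Optional at-risk counts.
#' @return An object of class `km_curve` (a data frame).
#' @export
km_curve <- function(times, surv, n_risk = NULL) {
  stopifnot(length(times) == length(surv))
  if (any(times < 0)) stop("`times` must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (any(surv > 1) || any(surv <= 0)) stop("`surv` must lie in (0, 1]")
  if (any(diff(surv) > 1e-12)) stop("`surv` must be non-increasing")
  out <- data.frame(time = times, surv = surv)
  if (!is.null(n_risk)) out$n_risk <- n_risk
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Hazard ratio
#'
#' @param value Positive hazard ratio.
#' @param source_label Free-text provenance label.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(value, source_label = "") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value <= 0) stop("hazard ratio must be positive")
  structure(list(value = value, source_label = source_label),
            class = "hazard_ratio")
}

#' Weibull survival function
#'
#' \eqn{S(t) = \exp(-\lambda t^k)}.
#'
#' @param params A [weibull_params()] object.
#' @param t Time(s) in months, `>= 0`.
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1`.
#' @export
weibull_survival <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  exp(-params$scale * t^params$shape)
}

#' Weibull hazard function
#'
#' \eqn{h(t) = \lambda k t^{k-1}} per month. For `shape < 1` the hazard is
#' singular at the origin, so `t = 0` is rejected in that case.
#'
#' @inheritParams weibull_survival
#' @param t Time(s) in months, `> 0` (`t = 0` allowed only when `shape >= 1`).
#' @return Hazard rates per month, `>= 0`.
#' @export
weibull_hazard <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  if (params$shape < 1 && any(t == 0))
    stop("hazard is singular at t = 0 when shape < 1")
  params$scale * params$shape * t^(params$shape - 1)
}

#' Median survival time of a Weibull model
#'
#' \eqn{(\ln 2 / \lambda)^{1/k}} months.
#'
#' @inheritParams weibull_survival
#' @return Median in months.
#' @export
weibull_median <- function(params) {
  stopifnot(inherits(params, "weibull_params"))
  (log(2) / params$scale)^(1 / params$shape)
}

#' Fit a Weibull model to Kaplan-Meier coordinates
#'
#' Least-squares fit of the complementary log-log transform:
#' \deqn{\ln(-\ln S(t)) = \ln\lambda + k \ln t,}
#' a linear regression of \eqn{\ln(-\ln S)} on \eqn{\ln t} over curve points
#' with \eqn{0 < S < 1} and \eqn{t > 0}. Deterministic and exact for points
#' lying on a true Weibull curve. Standard errors and the shape/scale
#' correlation are taken from the regression covariance (the scale SE by the
#' delta method from the intercept).
#'
#' When the curve carries at-risk counts the regression is iteratively
#' reweighted by the delta-method precision of the transformed response,
#' \eqn{w = (S \ln S)^2 n_{risk}}, with \eqn{S} taken from the current
#' fitted curve (two reweighting passes). This downweights the noisy KM
#' tail, where few subjects remain at risk, and noticeably reduces the
#' finite-sample bias of the scale estimate; without at-risk counts the
#' fit is ordinary (unweighted) least squares.
#'
#' @param curve A [km_curve()] with at least 3 usable points.
#' @return A [weibull_params()] object.
#' @export
fit_weibull_km <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  use <- curve$surv > 0 & curve$surv < 1 & curve$time > 0
  if (sum(use) < 3L)
    stop("need at least 3 points with 0 < surv < 1 and time > 0 to fit")
  x <- log(curve$time[use])
  y <- log(-log(curve$surv[use]))
  fit <- stats::lm(y ~ x)
  if (!is.null(curve$n_risk)) {
    nr <- curve$n_risk[use]
    for (pass in 1:2) {  # precision weights from the fitted curve, not the data
      s_fit <- exp(-exp(stats::fitted(fit)))
      fit <- stats::lm(y ~ x, weights = (s_fit * log(s_fit))^2 * nr)
    }
  }
  co <- stats::coef(fit)
  shape <- unname(co["x"])
  log_scale <- unname(co["(Intercept)"])
  if (shape <= 0) stop("fitted shape is non-positive; curve is not Weibull-like")
  # exact Weibull input gives a perfect fit; the zero-residual warning is noise
  vc <- suppressWarnings(stats::vcov(fit))
  scale <- exp(log_scale)
  se_log_scale <- sqrt(vc[1, 1])
  se_shape <- sqrt(vc[2, 2])
  corr <- if (se_log_scale > 0 && se_shape > 0)
    vc[1, 2] / (se_log_scale * se_shape) else 0
  weibull_params(shape = shape, scale = scale,
                 se_shape = se_shape,
                 se_scale = scale * se_log_scale,  # delta method
                 corr = corr)
}

#' Scale a Weibull model by a hazard ratio
#'
#' Under the shared-shape proportional-hazards assumption the comparator
#' arm keeps the reference shape and its scale is the reference scale
#' multiplied by the hazard ratio, so every hazard is multiplied by the
#' ratio. Standard error of the scale is multiplied by the same factor
#' (the hazard ratio is treated as a known constant here).
#'
#' @inheritParams weibull_survival
#' @param hr A [hazard_ratio()] object (or a single positive number).
#' @return A [weibull_params()] object.
#' @export
apply_hazard_ratio <- function(params, hr) {
  stopifnot(inherits(params, "weibull_params"))
  if (is.numeric(hr)) hr <- hazard_ratio(hr)
  stopifnot(inherits(hr, "hazard_ratio"))
  weibull_params(shape = params$shape,
                 scale = hr$value * params$scale,
                 se_shape = params$se_shape,
                 se_scale = hr$value * params$se_scale,
                 corr = params$corr)
}

#' Conditional per-cycle exit probability
#'
#' Probability of leaving the survival curve during cycle `cycle_index`
#' given presence at its start: \eqn{1 - S((i+1)L) / S(iL)} for cycle
#' length \eqn{L}. When the survivor function has underflowed to zero at
#' the cycle start the cohort is exhausted and the probability is 1 by
#' convention.
#'
#' @inheritParams weibull_survival
#' @param cycle_index Integer cycle index, `>= 0`.
#' @param cycle_length Cycle length in months (default 1).
#' @return A probability in `[0, 1]`.
#' @export
cycle_exit_probability <- function(params, cycle_index, cycle_length = 1) {
  stopifnot(inherits(params, "weibull_params"))
  if (cycle_length <= 0) stop("`cycle_length` must be positive")
  if (any(cycle_index < 0)) stop("`cycle_index` must be non-negative")
  s0 <- weibull_survival(params, cycle_index * cycle_length)
  s1 <- weibull_survival(params, (cycle_index + 1) * cycle_length)
  ifelse(s0 == 0, 1, pmin(1, pmax(0, 1 - s1 / s0)))
}
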