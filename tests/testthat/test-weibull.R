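test_that("survival function matches closed form and boundary behaviour", {
  expect_equal(weibull_survival(weibull_params(1, log(2)), 1), 0.5)
  expect_equal(weibull_survival(weibull_params(2.7, 0.3), 0), 1.0)
  expect_equal(weibull_survival(weibull_params(2, 0.01), 10), exp(-1),
               tolerance = 1e-12)
  expect_error(weibull_survival(weibull_params(1, 1), -1), "non-negative")
})

test_that("hazard function matches closed form; singular origin rejected", {
  p <- weibull_params(1, 0.2)
  expect_equal(weibull_hazard(p, c(0.5, 3, 40)), rep(0.2, 3))
  expect_equal(weibull_hazard(weibull_params(2, 0.01), 5), 0.1)
  expect_equal(weibull_hazard(weibull_params(1.5, 0.05), 4), 0.15)
  expect_error(weibull_hazard(weibull_params(0.8, 0.1), 0), "singular")
  expect_equal(weibull_hazard(weibull_params(1, 0.1), 0), 0.1)  # shape >= 1 ok
})

test_that("median inverts the survival function", {
  expect_equal(weibull_median(weibull_params(1, log(2))), 1.0)
  expect_equal(weibull_median(weibull_params(2, log(2))), 1.0)
  set.seed(11)
  for (i in 1:25) {
    p <- weibull_params(runif(1, 0.5, 3), runif(1, 0.005, 0.5))
    expect_equal(weibull_survival(p, weibull_median(p)), 0.5,
                 tolerance = 1e-9)
  }
})

test_that("parameter validation enforces the type invariants", {
  expect_error(weibull_params(-1, 0.1), "shape")
  expect_error(weibull_params(1, 0), "scale")
  expect_error(weibull_params(1, 1, corr = 1.5), "corr")
  expect_error(weibull_params(1, 1, se_shape = -0.1), "non-negative")
})

test_that("characteristic-life input converts to the rate parameterization", {
  # b = 10, k = 1.5  =>  lambda = 10^-1.5
  p <- weibull_params(1.5, 10, parameterization = "characteristic_life")
  expect_equal(p$scale, 10^-1.5)
  expect_equal(weibull_survival(p, 10), exp(-1), tolerance = 1e-12)
})

test_that("survival is non-increasing in time for valid parameters", {
  set.seed(21)
  grid <- seq(0, 60, by = 0.5)
  for (i in 1:20) {
    p <- weibull_params(runif(1, 0.4, 3.5), runif(1, 0.002, 0.6))
    expect_true(all(diff(weibull_survival(p, grid)) <= 0))
  }
})

test_that("cloglog fit recovers exact Weibull coordinates", {
  truth <- weibull_params(1.2, 0.05)
  t <- c(3, 6, 12, 24)
  fit <- fit_weibull_km(km_curve(t, weibull_survival(truth, t)))
  expect_equal(fit$shape, 1.2, tolerance = 1e-6)
  expect_equal(fit$scale, 0.05, tolerance = 1e-6)
  expect_lt(fit$se_shape, 1e-6)
})

test_that("cloglog fit recovers simulated truth; SEs shrink with n", {
  truth <- weibull_params(1.3, 0.04)
  ipd500 <- generate_ipd(truth, 500, censor_time = 60, seed = 42)
  f500 <- fit_weibull_km(km_estimate(ipd500))
  expect_equal(f500$shape, truth$shape, tolerance = 0.15)
  expect_equal(f500$scale, truth$scale, tolerance = 0.15)
  ipd50 <- generate_ipd(truth, 50, censor_time = 60, seed = 42)
  f50 <- fit_weibull_km(km_estimate(ipd50))
  expect_gt(f50$se_shape, f500$se_shape)
  expect_gt(f50$se_scale, f500$se_scale)
})

test_that("cloglog fit rejects unusable input", {
  expect_error(fit_weibull_km(km_curve(c(1, 2), c(0.9, 0.5))), "3 points")
  expect_error(fit_weibull_km(km_curve(c(1, 2, 3), c(1, 1, 1))), "3 points")
})

test_that("hazard-ratio scaling preserves shape and scales every hazard", {
  p <- weibull_params(1.1, 0.06)
  expect_equal(apply_hazard_ratio(p, hazard_ratio(1))[1:2], p[1:2])
  q <- apply_hazard_ratio(p, hazard_ratio(0.85))
  expect_equal(q$shape, 1.1)
  expect_equal(q$scale, 0.051)
  t <- seq(0.5, 60, by = 0.5)
  expect_equal(weibull_hazard(q, t) / weibull_hazard(p, t), rep(0.85, length(t)))
  # median identity: median_out = median_in * hr^(-1/shape)
  expect_equal(weibull_median(q), weibull_median(p) * 0.85^(-1 / 1.1),
               tolerance = 1e-12)
})

test_that("per-cycle exit probability is conditional and handles exhaustion", {
  p <- weibull_params(1, 0.1)
  expect_equal(cycle_exit_probability(p, 0:20), rep(1 - exp(-0.1), 21))
  p2 <- weibull_params(2, 0.01)
  expect_equal(cycle_exit_probability(p2, 0), 1 - weibull_survival(p2, 1))
  for (i in c(0, 3, 11)) {
    brute <- 1 - weibull_survival(p2, i + 1) / weibull_survival(p2, i)
    expect_equal(cycle_exit_probability(p2, i), brute, tolerance = 1e-12)
  }
  exhausted <- weibull_params(3, 5)  # S underflows within a few months
  expect_equal(cycle_exit_probability(exhausted, 50), 1)
})

test_that("KM curve container enforces its invariants", {
  expect_error(km_curve(c(2, 1), c(0.9, 0.8)), "increasing")
  expect_error(km_curve(c(1, 2), c(0.8, 0.9)), "non-increasing")
  expect_error(km_curve(c(1, 2), c(1.0, 0)), "\\(0, 1\\]")
})
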