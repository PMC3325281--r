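test_that("lognormal builder hits the target mean and range convention", {
  cfg <- fixture_config()
  spec <- build_distributions(cfg)
  d <- spec$costs$supportive_care_per_cycle
  expect_equal(d$sdlog, (log(1060) - log(480)) / (2 * 1.96), tolerance = 1e-12)
  set.seed(101)
  draws <- rlnorm(1e5, d$meanlog, d$sdlog)
  expect_equal(mean(draws), 735, tolerance = 0.01)
})

test_that("beta builder hits the target mean by method of moments", {
  cfg <- fixture_config()
  spec <- build_distributions(cfg)
  d <- spec$utilities$progressed
  expect_true(d$alpha > 0 && d$beta > 0)
  set.seed(102)
  draws <- rbeta(1e5, d$alpha, d$beta)
  expect_equal(mean(draws), 0.7314, tolerance = 0.01)
})

test_that("degenerate and invalid ranges are handled as specified", {
  cfg <- fixture_config()
  cfg$costs$operation$low <- cfg$costs$operation$high <- cfg$costs$operation$mean
  spec <- build_distributions(cfg)
  expect_equal(spec$costs$operation$kind, "degenerate")
  bad <- fixture_config()
  bad$costs$operation$low <- 7000  # low > high
  expect_error(build_distributions(bad), "high <= low|low <= mean")
  badu <- fixture_config()
  badu$utilities$progressed$mean <- 0.5
  badu$utilities$progressed$low <- 0
  badu$utilities$progressed$high <- 3.4  # variance beyond beta support
  expect_error(suppressWarnings(build_distributions(badu)),
               "beta|\\[0, 1\\]")
})

test_that("a degenerate PSA reproduces the base case exactly and seeds reproduce draws", {
  cfg <- fixture_config()
  spec0 <- build_distributions(cfg, degenerate = TRUE)
  ps <- run_psa(cfg, n_draws = 3, seed = 9, spec = spec0)
  base <- lapply(gbm_strategies(), function(s)
    evaluate_strategy(cfg, "overall", s)$outcome)
  names(base) <- gbm_strategies()
  for (s in gbm_strategies()) {
    expect_equal(unique(ps$cost[ps$strategy == s]), base[[s]]$cost)
    expect_equal(unique(ps$qaly[ps$strategy == s]), base[[s]]$qaly)
  }
  a <- run_psa(cfg, n_draws = 8, seed = 4)
  b <- run_psa(cfg, n_draws = 8, seed = 4)
  expect_identical(a, b)
  c2 <- run_psa(cfg, n_draws = 8, seed = 5)
  expect_false(identical(a$cost, c2$cost))
})

test_that("PSA draw means stay near the base case", {
  cfg <- fixture_config()
  ps <- run_psa(cfg, n_draws = 200, seed = 12)
  base <- lapply(gbm_strategies(), function(s)
    evaluate_strategy(cfg, "overall", s)$outcome)
  names(base) <- gbm_strategies()
  for (s in gbm_strategies()) {
    expect_equal(mean(ps$cost[ps$strategy == s]), base[[s]]$cost,
                 tolerance = 0.10)
    expect_equal(mean(ps$qaly[ps$strategy == s]), base[[s]]$qaly,
                 tolerance = 0.10)
  }
})

test_that("acceptability curves normalize, bound and obey WTP limits", {
  one <- data.frame(draw = c(1, 1, 1), strategy = c("RT", "RT+NT", "RT+TMZ"),
                    cost = c(10, 20, 30), qaly = c(0.5, 0.6, 1.0))
  class(one) <- c("psa_draws", "data.frame")
  cc1 <- ceac(one, c(1, 1e9))
  expect_true(all(cc1$probability %in% c(0, 1)))
  expect_equal(cc1$probability[cc1$wtp == 1],        c(1, 0, 0))  # cheapest
  expect_equal(cc1$probability[cc1$wtp == 1e9],      c(0, 0, 1))  # max QALY
  cfg <- fixture_config()
  ps <- run_psa(cfg, n_draws = 60, seed = 31)
  grid <- seq(2000, 120000, by = 2000)
  cc <- ceac(ps, grid)
  sums <- as.numeric(tapply(cc$probability, cc$wtp, sum))
  expect_equal(sums, rep(1, length(grid)), tolerance = 1e-12)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # brute-force argmax at one threshold
  w <- 40000
  nmb <- matrix(ps$qaly * w - ps$cost, ncol = 3, byrow = TRUE)
  brute <- table(factor(max.col(nmb), levels = 1:3)) / nrow(nmb)
  expect_equal(cc$probability[cc$wtp == w], as.numeric(brute))
})

test_that("confidence ellipse has chi-square geometry and 95% coverage", {
  r2 <- qchisq(0.95, 2)
  set.seed(77)
  n <- 1e4
  de <- rnorm(n, 0.3, 1); dc <- rnorm(n, 100, 1)  # isotropic unit covariance
  dr <- data.frame(draw = rep(1:n, each = 2),
                   strategy = rep(c("A", "B"), n),
                   cost = as.vector(rbind(dc, 0)),
                   qaly = as.vector(rbind(de, 0)))
  class(dr) <- c("psa_draws", "data.frame")
  el <- ci_ellipse(dr, c("A", "B"))
  expect_equal(el$axes[1], sqrt(r2), tolerance = 0.05)
  expect_equal(el$axes[2], sqrt(r2), tolerance = 0.05)
  inside <- mahalanobis(cbind(de, dc), el$center, el$cov) <= r2
  expect_equal(mean(inside), 0.95, tolerance = 0.011)
  same <- dr; same$cost <- 1; same$qaly <- 1
  expect_error(ci_ellipse(same, c("A", "B")), "singular")
})

test_that("one-way analysis is monotone in the TMZ price and validates ids", {
  cfg <- fixture_config()
  ow0 <- one_way(cfg, "cost.tmz_100mg", 156, 156)
  expect_equal(ow0$width, 0)
  ow <- one_way(cfg, "cost.tmz_100mg", 140, 171)
  expect_gt(ow$nhb_low, ow$nhb_high)  # dearer TMZ lowers net health benefit
  expect_error(one_way(cfg, "cost.nonexistent", 1, 2), "unknown parameter")
})
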