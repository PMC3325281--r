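test_that("disease-free utility follows the treatment phase", {
  ut <- utility_table()
  expect_equal(pf_phase_utility("RT", 0, ut), 0.8239)
  expect_equal(pf_phase_utility("RT+TMZ", 0, ut), 0.7426)
  expect_equal(pf_phase_utility("RT+NT", 1, ut), 0.7426)
  expect_equal(pf_phase_utility("RT", 12, ut), 0.8872)
  expect_equal(pf_phase_utility("RT+TMZ", 2, ut), 0.8872)  # off month
  expect_equal(pf_phase_utility("RT+TMZ", 5, ut), 0.7331)  # adjuvant
  expect_equal(pf_phase_utility("RT+NT", 30, ut), 0.7331)  # ACNU continues
  expect_error(pf_phase_utility("XYZ", 0, ut))
})

test_that("progressed utility applies the monthly decrement per entry cohort", {
  ut <- utility_table()
  # everyone progressed this cycle: no decrement yet
  tr <- make_trace(pf = c(1, 0.7, 0.7), prog = c(0, 0.3, 0.3),
                   dead = c(0, 0, 0), new_prog = c(0, 0.3, 0))
  expect_equal(progressed_expected_utility(tr, 1, ut), 0.7314)
  # the same single entry cohort, five cycles later
  tr2 <- make_trace(pf = c(1, rep(0.7, 7)), prog = c(0, rep(0.3, 7)),
                    dead = rep(0, 8), new_prog = c(0, 0.3, rep(0, 6)))
  expect_equal(progressed_expected_utility(tr2, 6, ut), 0.7314 - 0.10)
  # decrement floors at zero, never negative
  tr3 <- make_trace(pf = c(1, rep(0.7, 44)), prog = c(0, rep(0.3, 44)),
                    dead = rep(0, 45), new_prog = c(0, 0.3, rep(0, 43)))
  expect_equal(progressed_expected_utility(tr3, 41, ut), 0)
  # empty state contributes zero by convention
  expect_equal(progressed_expected_utility(tr, 0, ut), 0)
})

test_that("entry-cohort weights are a proper distribution once progression begins", {
  cfg <- fixture_config()
  m <- cohort_models(cfg, "overall")
  tr <- run_cohort(m$RT$pfs, m$RT$os, 60)
  for (cyc in c(5, 20, 50)) {
    w <- gbmcea:::prog_entry_weights(tr, cyc)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("twelve untreated disease-free cycles accrue 0.8872 QALYs", {
  ut_flat <- utility_table(pf_rt = 0.8872, pf_rt_tmz = 0.8872,
                           pf_rt_nt = 0.8872, pf_tmz_adjuvant = 0.8872,
                           pf_nt_adjuvant = 0.8872)
  tr <- make_trace(pf = rep(1, 13), prog = rep(0, 13), dead = rep(0, 13))
  expect_equal(total_qaly(tr, "RT", ut_flat), 0.8872)
  ut_zero <- utility_table(pf_no_treatment = 0, pf_rt = 0, pf_rt_tmz = 0,
                           pf_rt_nt = 0, pf_tmz_adjuvant = 0,
                           pf_nt_adjuvant = 0, progressed = 0)
  expect_equal(total_qaly(tr, "RT", ut_zero), 0)
})

test_that("zero decrement makes the progressed utility entry-independent", {
  ut0 <- utility_table(progression_decrement = 0)
  tr <- make_trace(pf = c(1, rep(0.5, 20)), prog = c(0, rep(0.4, 20)),
                   dead = c(0, rep(0.1, 20)),
                   new_prog = c(0, 0.4, rep(0, 19)))
  for (cyc in c(1, 8, 19))
    expect_equal(progressed_expected_utility(tr, cyc, ut0), 0.7314)
})

test_that("QALY totals are bounded and monotone in utility weights", {
  cfg <- fixture_config()
  m <- cohort_models(cfg, "overall")
  tr <- run_cohort(m$`RT+TMZ`$pfs, m$`RT+TMZ`$os, 60)
  base <- total_qaly(tr, "RT+TMZ", cfg$utilities)
  expect_gte(base, 0)
  expect_lte(base, 60 / 12)
  for (nm in c("pf_no_treatment", "pf_rt_tmz", "pf_tmz_adjuvant", "progressed")) {
    args <- list(list(mean = min(1, cfg$utilities[[nm]]$mean + 0.05),
                      low = 0, high = 1))
    names(args) <- nm
    raised <- do.call(utility_table, args)
    expect_gte(total_qaly(tr, "RT+TMZ", raised), base - 1e-12)
  }
})

test_that("QALY ordering matches the base case: RT < RT+NT < RT+TMZ overall", {
  cfg <- fixture_config()
  q <- vapply(gbm_strategies(), function(s)
    evaluate_strategy(cfg, "overall", s)$outcome$qaly, numeric(1))
  expect_true(q[["RT"]] < q[["RT+NT"]] && q[["RT+NT"]] < q[["RT+TMZ"]])
})
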