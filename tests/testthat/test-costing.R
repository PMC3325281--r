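test_that("Mosteller body surface area", {
  expect_equal(round(body_surface_area(65, 1.64), 2), 1.72)
  expect_equal(body_surface_area(36, 1.00), 1.00)
  expect_equal(body_surface_area(80, 1.80), 2.00)
  expect_error(body_surface_area(0, 1.6), "positive")
})

test_that("TMZ daily cost uses achievable capsule doses at the cheapest composition", {
  co <- cost_table()
  expect_equal(tmz_daily_cost(0, co), 0)
  expect_equal(tmz_daily_cost(100, co), 156)
  # 129.2 mg -> nearest 20 mg multiple is 120 -> one 100 mg + one 20 mg
  expect_equal(tmz_daily_cost(129.2, co), 156 + 38)
  # ties round up: 110 -> 120
  expect_equal(tmz_daily_cost(110, co), 156 + 38)
  # 90 -> 100 mg; one capsule beats five 20 mg capsules (156 < 190)
  expect_equal(tmz_daily_cost(90, co), 156)
  expect_equal(tmz_daily_cost(129.2, co, rounding = "up"), 156 + 2 * 38)
  expect_equal(tmz_daily_cost(129.2, co, rounding = "exact"), 129.2 / 20 * 38)
})

test_that("ACNU cost is whole vials of 25 mg", {
  co <- cost_table()
  prof <- patient_profile()  # BSA 1.72: 172 mg -> 7 vials
  expect_equal(acnu_administration_cost(100, prof, co), 7 * 57)
  expect_equal(acnu_administration_cost(0, prof, co), 0)
  prof1 <- patient_profile(bsa = 1)
  expect_equal(acnu_administration_cost(25, prof1, co), 57)
})

test_that("radiotherapy schedule delivers 30 fractions of 2 Gy (60 Gy)", {
  sch <- strategy_schedule("RT")
  expect_equal(sum(sch$rt_fractions_by_cycle), 30)
})

test_that("cycle cost matches hand-computed components", {
  co <- cost_table()
  prof <- patient_profile()
  # fully disease-free first cycle, with the initial-surgery option enabled
  tr <- make_trace(pf = c(1, 1, 1), prog = c(0, 0, 0), dead = c(0, 0, 0))
  sch <- strategy_schedule("RT", include_initial_surgery = TRUE,
                           follow_up_policy = "post_treatment")
  expect_equal(cycle_cost(sch, tr, 0, co, prof),
               20 * 100 + 0.84 * 5150 + 0.16 * 1180)
  # everyone dead: nothing accrues
  tr_dead <- make_trace(pf = c(1, 0, 0, 0), prog = c(0, 0, 0, 0),
                        dead = c(0, 1, 1, 1), new_prog = c(0, 0, 0, 0))
  expect_equal(cycle_cost(strategy_schedule("RT+TMZ"), tr_dead, 2, co, prof), 0)
  # progressed occupancy 1, second line 100% supportive care
  tr_prog <- make_trace(pf = c(1, 0, 0, 0), prog = c(0, 1, 1, 1),
                        dead = c(0, 0, 0, 0), new_prog = c(0, 1, 0, 0))
  sch_bsc <- strategy_schedule("RT", second_line_mix = c(chemo = 0, surgery = 0,
                                                         bsc = 1))
  expect_equal(cycle_cost(sch_bsc, tr_prog, 2, co, prof), 735)
  expect_error(cycle_cost(sch_bsc, tr_prog, 5, co, prof), "out of range")
})

test_that("total cost is linear in unit prices and zero for a free system", {
  cfg <- fixture_config()
  prof <- cfg$profile
  m <- cohort_models(cfg, "overall")
  tr <- run_cohort(m$`RT+TMZ`$pfs, m$`RT+TMZ`$os, 60)
  sch <- strategy_schedule("RT+TMZ")  # defaults mirror the default config
  zero <- cost_table(operation = 0, biopsy = 0, rt_per_fraction = 0,
                     tmz_100mg = 0, tmz_20mg = 0, acnu_25mg = 0,
                     second_line_per_cycle = 0, supportive_care_per_cycle = 0,
                     follow_up_per_unit = 0, sae_hematologic = 0,
                     sae_infection = 0, sae_gastrointestinal = 0)
  expect_equal(total_cost(sch, tr, zero, prof), 0)
  base <- total_cost(sch, tr, cfg$costs, prof)
  doubled <- cost_table(file = NULL)
  dbl <- lapply(unclass(cfg$costs), function(it)
    list(mean = 2 * it$mean, low = 2 * it$low, high = 2 * it$high))
  doubled <- do.call(cost_table, dbl)
  expect_equal(total_cost(sch, tr, doubled, prof), 2 * base, tolerance = 1e-9)
})

test_that("strategy totals are ordered RT < RT+NT < RT+TMZ in the overall cohort", {
  cfg <- fixture_config()
  evs <- lapply(gbm_strategies(), function(s)
    evaluate_strategy(cfg, "overall", s)$outcome)
  costs <- vapply(evs, `[[`, numeric(1), "cost")
  expect_true(costs[1] < costs[2] && costs[2] < costs[3])
})

test_that("schedule mix validation rejects malformed proportions", {
  expect_error(strategy_schedule("RT", second_line_mix = c(chemo = 0.5,
                                                           surgery = 0.5,
                                                           bsc = 0.5)),
               "sum to 1")
  expect_error(strategy_schedule("RT", sae_probabilities = c(hematologic = 1.2,
                                                             infection = 0,
                                                             gastrointestinal = 0)),
               "\\[0, 1\\]")
})
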