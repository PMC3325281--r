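#' Unit-cost table (2009 USD)
#'
#' Direct medical unit costs with plausible ranges, from the healthcare-system
#' perspective. Each item is a `list(mean, low, high)` in US dollars
#' (converted from CNY at 6.50 where applicable). Defaults are the package's
#' shipped cost fixture; any item can be overridden.
#'
#' @param ... Named overrides, each a numeric vector/list with elements
#'   `mean`, `low`, `high` (a single number is taken as a degenerate item).
#' @param file Optional YAML file to read instead of the shipped fixture.
#' @return An object of class `cost_table`: a named list of items.
#' @export
cost_table <- function(..., file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "costs.yaml", package = "gbmcea")
  raw <- yaml::read_yaml(file)
  items <- lapply(raw$items, function(x) x[c("mean", "low", "high")])
  over <- list(...)
  for (nm in names(over)) {
    x <- over[[nm]]
    if (is.numeric(x) && length(x) == 1L) x <- list(mean = x, low = x, high = x)
    items[[nm]] <- as.list(x)[c("mean", "low", "high")]
  }
  for (nm in names(items)) {
    it <- items[[nm]]
    if (it$mean < 0 || it$low < 0) stop("costs must be non-negative: ", nm)
    if (!(it$low <= it$mean && it$mean <= it$high))
      stop("require low <= mean <= high for cost item ", nm)
  }
  structure(items, class = "cost_table")
}

#' Typical patient profile
#'
#' Chemotherapy doses are scaled by body surface area (BSA, Mosteller).
#' The default profile (65 kg, 1.64 m) gives a BSA of 1.72 m^2.
#'
#' @param weight Body weight in kg.
#' @param height Height in metres.
#' @param bsa Optional BSA override in m^2 (used directly in sensitivity
#'   analyses); computed from weight and height when `NULL`.
#' @return An object of class `patient_profile` with fields `weight`,
#'   `height`, `bsa`.
#' @export
patient_profile <- function(weight = 65, height = 1.64, bsa = NULL) {
  if (is.null(bsa)) bsa <- body_surface_area(weight, height)
  if (bsa <= 0) stop("BSA must be positive")
  structure(list(weight = weight, height = height, bsa = bsa),
            class = "patient_profile")
}

#' Body surface area (Mosteller)
#'
#' \eqn{\sqrt{weight \times height_{cm} / 3600}} square metres.
#'
#' @param weight Body weight in kg, `> 0`.
#' @param height Height in metres, `> 0`.
#' @return BSA in m^2.
#' @examples
#' body_surface_area(65, 1.64)  # 1.72
#' @export
body_surface_area <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  sqrt(weight * (height * 100) / 3600)
}

#' Daily temozolomide acquisition cost
#'
#' The prescribed dose (mg) is mapped to an achievable capsule dose --
#' a multiple of 20 mg from 100 mg and 20 mg capsules -- and costed at the
#' cheapest capsule composition (found by exhaustive search over the number
#' of 100 mg capsules). The rounding convention is configurable:
#' `"nearest"` rounds to the nearest 20 mg multiple with ties rounding up,
#' `"up"` always rounds up (no dose splitting, wastage-conservative; the
#' package's default costing convention, see the methods vignette), and
#' `"exact"` prices the exact milligram amount pro rata at the 20 mg
#' capsule's unit price.
#'
#' @param dose_mg Prescribed dose in mg, `>= 0`.
#' @param costs A [cost_table()].
#' @param rounding `"nearest"`, `"up"` or `"exact"`.
#' @return Cost in dollars.
#' @examples
#' co <- cost_table()
#' tmz_daily_cost(100, co)    # one 100 mg capsule
#' tmz_daily_cost(129.2, co)  # rounds to 120 mg: one 100 mg + one 20 mg
#' @export
tmz_daily_cost <- function(dose_mg, costs,
                           rounding = c("nearest", "up", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(costs, "cost_table"))
  if (dose_mg < 0) stop("`dose_mg` must be non-negative")
  if (dose_mg == 0) return(0)
  p100 <- costs$tmz_100mg$mean
  p20 <- costs$tmz_20mg$mean
  if (rounding == "exact") return(dose_mg / 20 * p20)
  units20 <- switch(rounding,
                    nearest = floor(dose_mg / 20 + 0.5),  # ties round up
                    up = ceiling(dose_mg / 20))
  target <- 20 * units20
  if (target == 0) return(0)
  best <- Inf
  for (n100 in 0:ceiling(target / 100)) {
    rem <- target - 100 * n100
    n20 <- if (rem <= 0) 0 else ceiling(rem / 20)
    best <- min(best, n100 * p100 + n20 * p20)
  }
  best
}

#' Cost of one nimustine (ACNU) administration
#'
#' Whole 25 mg vials: `ceiling(dose x BSA / 25)` vials at the 25 mg unit
#' price.
#'
#' @param dose_mg_per_m2 Dose in mg/m^2, `>= 0`.
#' @param profile A [patient_profile()].
#' @param costs A [cost_table()].
#' @return Cost in dollars.
#' @export
acnu_administration_cost <- function(dose_mg_per_m2, profile, costs) {
  stopifnot(inherits(profile, "patient_profile"), inherits(costs, "cost_table"))
  if (dose_mg_per_m2 < 0) stop("dose must be non-negative")
  if (dose_mg_per_m2 == 0) return(0)
  ceiling(dose_mg_per_m2 * profile$bsa / 25) * costs$acnu_25mg$mean
}

#' Treatment schedule for a first-line strategy
#'
#' Encodes when each treatment component is delivered, per monthly cycle,
#' together with the second-line and adverse-event conventions used in
#' costing. Defaults implement the modelled regimens:
#'
#' * Radiotherapy (all strategies): 60 Gy in 30 fractions of 2 Gy,
#'   5 days/week over 6 weeks, mapped to 20 fractions in cycle 0 and 10 in
#'   cycle 1.
#' * TMZ strategy: concomitant TMZ 75 mg/m^2 daily for the 42 days of
#'   radiotherapy (30 days in cycle 0, 12 in cycle 1), cycle 2 off, then six
#'   adjuvant cycles (cycles 3-8) of 5 days each at 150 mg/m^2 in the first
#'   adjuvant cycle and 200 mg/m^2 thereafter.
#' * NT strategy: nimustine 100 mg/m^2 intravenously every 6 weeks until
#'   progression, prorated to a monthly cost (x 30/42) while disease-free.
#' * Second line (at progression): a mix of PCV chemotherapy ($ per 8-week
#'   cycle prorated x 30/56, for at most `pcv_max_cycles` cycles since
#'   progression), re-operation (one-off at progression entry) and best
#'   supportive care per cycle.
#' * Expected severe-adverse-event cost (sum of probability x unit cost)
#'   is spread over the chemotherapy treatment cycles, chemotherapy
#'   strategies only.
#'
#' @param strategy `"RT"`, `"RT+NT"` or `"RT+TMZ"`.
#' @param rt_fractions_by_cycle Radiotherapy fractions per cycle.
#' @param concomitant_tmz_days_by_cycle Concomitant TMZ days per cycle
#'   (TMZ strategy).
#' @param concomitant_dose_mg_m2 Concomitant daily dose (mg/m^2).
#' @param adjuvant_cycles Cycle indices of adjuvant TMZ cycles.
#' @param adjuvant_doses_mg_m2 Dose (mg/m^2) for each adjuvant cycle.
#' @param adjuvant_days_per_cycle Dosing days per adjuvant cycle.
#' @param acnu_dose_mg_m2 ACNU dose (mg/m^2) per administration.
#' @param acnu_interval_weeks Weeks between ACNU administrations.
#' @param sae_probabilities Named per-event probabilities
#'   (`hematologic`, `infection`, `gastrointestinal`).
#' @param sae_cycles Cycles over which the expected SAE cost is spread.
#' @param second_line_mix Named proportions (`chemo`, `surgery`, `bsc`)
#'   summing to 1.
#' @param surgery_mix Named proportions (`operation`, `biopsy`) summing to 1,
#'   used for (re-)operation costing.
#' @param pcv_max_cycles Maximum number of 8-week PCV cycles per progressor.
#' @param capsule_rounding TMZ rounding convention, see [tmz_daily_cost()].
#' @param follow_up_policy `"all_pf"` charges the follow-up unit to every
#'   disease-free cycle; `"post_treatment"` only after first-line treatment
#'   ends.
#' @param include_initial_surgery Charge the initial operation/biopsy at
#'   cycle 0 (default `FALSE`: the cohort enters the model after surgery).
#' @return An object of class `strategy_schedule`.
#' @export
strategy_schedule <- function(strategy = c("RT", "RT+NT", "RT+TMZ"),
                              rt_fractions_by_cycle = c(20, 10),
                              concomitant_tmz_days_by_cycle = c(30, 12),
                              concomitant_dose_mg_m2 = 75,
                              adjuvant_cycles = 3:8,
                              adjuvant_doses_mg_m2 = c(150, rep(200, 5)),
                              adjuvant_days_per_cycle = 5,
                              acnu_dose_mg_m2 = 100,
                              acnu_interval_weeks = 6,
                              sae_probabilities = c(hematologic = 0.12,
                                                    infection = 0.03,
                                                    gastrointestinal = 0.03),
                              sae_cycles = 0:8,
                              second_line_mix = c(chemo = 0.4, surgery = 0.1,
                                                  bsc = 0.5),
                              surgery_mix = c(operation = 0.84, biopsy = 0.16),
                              pcv_max_cycles = 6,
                              capsule_rounding = "up",
                              follow_up_policy = c("all_pf", "post_treatment"),
                              include_initial_surgery = FALSE) {
  strategy <- match.arg(strategy)
  follow_up_policy <- match.arg(follow_up_policy)
  check_mix <- function(x, nm) {
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-8)
      stop("`", nm, "` proportions must lie in [0,1] and sum to 1")
  }
  check_mix(second_line_mix, "second_line_mix")
  check_mix(surgery_mix, "surgery_mix")
  if (any(sae_probabilities < 0) || any(sae_probabilities > 1))
    stop("SAE probabilities must lie in [0, 1]")
  if (any(rt_fractions_by_cycle < 0) || any(concomitant_tmz_days_by_cycle < 0))
    stop("schedule counts must be non-negative")
  if (length(adjuvant_doses_mg_m2) != length(adjuvant_cycles))
    stop("one adjuvant dose per adjuvant cycle required")
  structure(list(strategy = strategy,
                 rt_fractions_by_cycle = rt_fractions_by_cycle,
                 concomitant_tmz_days_by_cycle = concomitant_tmz_days_by_cycle,
                 concomitant_dose_mg_m2 = concomitant_dose_mg_m2,
                 adjuvant_cycles = adjuvant_cycles,
                 adjuvant_doses_mg_m2 = adjuvant_doses_mg_m2,
                 adjuvant_days_per_cycle = adjuvant_days_per_cycle,
                 acnu_dose_mg_m2 = acnu_dose_mg_m2,
                 acnu_interval_weeks = acnu_interval_weeks,
                 sae_probabilities = sae_probabilities,
                 sae_cycles = sae_cycles,
                 second_line_mix = second_line_mix,
                 surgery_mix = surgery_mix,
                 pcv_max_cycles = pcv_max_cycles,
                 capsule_rounding = capsule_rounding,
                 follow_up_policy = follow_up_policy,
                 include_initial_surgery = include_initial_surgery),
            class = "strategy_schedule")
}

# first cycle after which first-line treatment has ended (for follow-up policy)
treatment_end_cycle <- function(schedule) {
  switch(schedule$strategy,
         "RT" = length(schedule$rt_fractions_by_cycle),
         "RT+TMZ" = max(schedule$adjuvant_cycles) + 1L,
         "RT+NT" = Inf)  # ACNU continues until progression
}

#' Expected cost of one model cycle
#'
#' Expected direct medical cost per starting cohort member accrued during
#' cycle `cycle` (start-of-cycle occupancies, no half-cycle correction).
#' Components: radiotherapy fractions, concomitant and adjuvant TMZ, ACNU
#' (all weighted by the disease-free occupancy and stopping at progression),
#' expected SAE management cost, routine follow-up while disease-free, and
#' the progressed-state blend of prorated PCV chemotherapy (entry-cohort
#' capped), amortized re-operation (one-off at progression entry) and best
#' supportive care.
#'
#' @param strategy_schedule A [strategy_schedule()].
#' @param trace A [run_cohort()] trace.
#' @param cycle Cycle index in `0..horizon-1`.
#' @param costs A [cost_table()].
#' @param profile A [patient_profile()].
#' @return Expected dollars for the cycle.
#' @export
cycle_cost <- function(strategy_schedule, trace, cycle, costs, profile) {
  sch <- strategy_schedule
  stopifnot(inherits(sch, "strategy_schedule"), inherits(trace, "cohort_trace"),
            inherits(costs, "cost_table"), inherits(profile, "patient_profile"))
  horizon <- max(trace$cycle)
  if (cycle < 0 || cycle >= horizon) stop("`cycle` out of range 0..horizon-1")
  pf <- trace$pf[cycle + 1L]
  prog <- trace$prog[cycle + 1L]
  total <- 0

  if (cycle == 0 && sch$include_initial_surgery)
    total <- total + sch$surgery_mix[["operation"]] * costs$operation$mean +
      sch$surgery_mix[["biopsy"]] * costs$biopsy$mean

  # radiotherapy
  if (cycle < length(sch$rt_fractions_by_cycle))
    total <- total + sch$rt_fractions_by_cycle[cycle + 1L] *
      costs$rt_per_fraction$mean * pf

  if (sch$strategy == "RT+TMZ") {
    if (cycle < length(sch$concomitant_tmz_days_by_cycle))
      total <- total + sch$concomitant_tmz_days_by_cycle[cycle + 1L] *
        tmz_daily_cost(sch$concomitant_dose_mg_m2 * profile$bsa, costs,
                       sch$capsule_rounding) * pf
    adj <- match(cycle, sch$adjuvant_cycles)
    if (!is.na(adj))
      total <- total + sch$adjuvant_days_per_cycle *
        tmz_daily_cost(sch$adjuvant_doses_mg_m2[adj] * profile$bsa, costs,
                       sch$capsule_rounding) * pf
  }

  if (sch$strategy == "RT+NT")
    total <- total + acnu_administration_cost(sch$acnu_dose_mg_m2, profile, costs) *
      30 / (7 * sch$acnu_interval_weeks) * pf

  # expected SAE management cost, chemotherapy strategies only
  if (sch$strategy != "RT" && cycle %in% sch$sae_cycles) {
    sae_total <- sch$sae_probabilities[["hematologic"]] * costs$sae_hematologic$mean +
      sch$sae_probabilities[["infection"]] * costs$sae_infection$mean +
      sch$sae_probabilities[["gastrointestinal"]] * costs$sae_gastrointestinal$mean
    total <- total + sae_total / length(sch$sae_cycles) * pf
  }

  # routine follow-up while disease-free
  fu_on <- if (sch$follow_up_policy == "all_pf") TRUE
           else cycle >= treatment_end_cycle(sch)
  if (fu_on) total <- total + costs$follow_up_per_unit$mean * pf

  # progressed state: second-line blend
  if (prog > 0) {
    w <- prog_entry_weights(trace, cycle)
    s <- seq_along(w) - 1L
    # PCV continues for at most pcv_max_cycles 8-week cycles after entry
    pcv_months <- sch$pcv_max_cycles * 56 / 30
    chemo_frac <- sum(w[(cycle - s) < pcv_months])
    total <- total + prog *
      (sch$second_line_mix[["chemo"]] * costs$second_line_per_cycle$mean *
         30 / 56 * chemo_frac +
       sch$second_line_mix[["bsc"]] * costs$supportive_care_per_cycle$mean)
  }
  # re-operation one-off for the surgical fraction of this cycle's entrants
  total <- total + trace$new_prog[cycle + 1L] *
    sch$second_line_mix[["surgery"]] * costs$operation$mean

  unname(total)
}

#' Total cost over the model horizon
#'
#' Sum of [cycle_cost()] over cycles `0..horizon-1`. Future costs are not
#' discounted by default; a positive annual `discount_rate` applies the
#' factor \eqn{(1+r)^{-t/12}}.
#'
#' @inheritParams cycle_cost
#' @param discount_rate Annual discount rate (default 0).
#' @return Total expected dollars per starting cohort member.
#' @export
total_cost <- function(strategy_schedule, trace, costs, profile,
                       discount_rate = 0) {
  horizon <- max(trace$cycle)
  cycles <- 0:(horizon - 1L)
  per_cycle <- vapply(cycles, function(cyc)
    cycle_cost(strategy_schedule, trace, cyc, costs, profile), numeric(1))
  disc <- (1 + discount_rate)^(-cycles / 12)
  sum(per_cycle * disc)
}
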