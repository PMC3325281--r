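#' Survival models for every strategy in a cohort
#'
#' Resolves the PFS and OS Weibull models of the three strategies for one
#' cohort from the configuration's parameter table:
#' * RT and RT+TMZ OS come directly from the table (an error identifies
#'   the missing cohort/arm/endpoint otherwise);
#' * missing subgroup PFS rows are imputed with [impute_subgroup_pfs()]
#'   from the overall cohort's PFS/OS of the same arm;
#' * the RT+NT arm is derived from RT by [apply_hazard_ratio()] with the
#'   configured nitrosourea hazard ratios (shared-shape indirect
#'   comparison).
#'
#' @param config A [default_config()]-style configuration.
#' @param cohort Cohort label, one of [gbm_cohorts()].
#' @return A named list (`RT`, `RT+NT`, `RT+TMZ`) of lists with elements
#'   `pfs`, `os` and `pfs_imputed`.
#' @export
cohort_models <- function(config, cohort) {
  stopifnot(inherits(config, "gbm_config"))
  p <- config$params
  horizon <- config$settings$horizon
  get_arm <- function(arm) {
    os <- param_row(p, cohort, arm, "OS")
    if (is.null(os))
      stop(sprintf("missing parameter row: cohort=%s arm=%s endpoint=OS",
                   cohort, arm))
    pfs <- param_row(p, cohort, arm, "PFS")
    imputed <- FALSE
    if (is.null(pfs)) {
      ov_pfs <- param_row(p, "overall", arm, "PFS")
      ov_os <- param_row(p, "overall", arm, "OS")
      if (is.null(ov_pfs) || is.null(ov_os))
        stop(sprintf("cannot impute PFS for cohort=%s arm=%s: overall %s rows missing",
                     cohort, arm, arm))
      pfs <- impute_subgroup_pfs(ov_pfs, ov_os, os, horizon)
      imputed <- TRUE
    }
    list(pfs = pfs, os = os, pfs_imputed = imputed)
  }
  rt <- get_arm("RT")
  tmz <- get_arm("RT+TMZ")
  nt <- list(pfs = apply_hazard_ratio(rt$pfs, config$hr_nt$pfs$mean),
             os = apply_hazard_ratio(rt$os, config$hr_nt$os$mean),
             pfs_imputed = rt$pfs_imputed)
  list("RT" = rt, "RT+NT" = nt, "RT+TMZ" = tmz)
}

# Build the strategy schedule implied by a configuration.
schedule_from_config <- function(strategy, config) {
  strategy_schedule(
    strategy = strategy,
    sae_probabilities = c(
      hematologic = config$sae_probs$hematologic$mean,
      infection = config$sae_probs$infection$mean,
      gastrointestinal = config$sae_probs$gastrointestinal$mean),
    second_line_mix = c(chemo = config$second_line_mix$chemo$mean,
                        surgery = config$second_line_mix$surgery$mean,
                        bsc = config$second_line_mix$bsc$mean),
    surgery_mix = config$surgery_mix,
    capsule_rounding = config$settings$capsule_rounding,
    follow_up_policy = config$settings$follow_up_policy,
    include_initial_surgery = config$settings$include_initial_surgery)
}

#' Evaluate one strategy in one cohort
#'
#' Runs the cohort trace, costing and QALY accrual for a single strategy.
#'
#' @inheritParams cohort_models
#' @param strategy One of [gbm_strategies()].
#' @param models Optional pre-computed [cohort_models()] output.
#' @return A list with `outcome` (a [strategy_outcome()]), `trace` and
#'   `pfs_imputed`.
#' @export
evaluate_strategy <- function(config, cohort, strategy, models = NULL) {
  if (is.null(models)) models <- cohort_models(config, cohort)
  m <- models[[strategy]]
  if (is.null(m)) stop("unknown strategy '", strategy, "'; valid: ",
                       paste(gbm_strategies(), collapse = ", "))
  sch <- schedule_from_config(strategy, config)
  tr <- run_cohort(m$pfs, m$os, config$settings$horizon)
  # renormalize mix proportions in case PSA draws perturbed them
  cost <- total_cost(sch, tr, config$costs, config$profile,
                     config$settings$discount_rate)
  qaly <- total_qaly(tr, strategy, config$utilities, sch,
                     config$settings$discount_rate)
  list(outcome = strategy_outcome(strategy, cost, qaly), trace = tr,
       pfs_imputed = m$pfs_imputed)
}

#' Base-case analysis across cohorts and strategies
#'
#' Runs survival resolution (with PFS imputation where needed), the cohort
#' trace, costing and QALY accrual for every cohort x strategy, and adds
#' the three pairwise ICER columns of the standard results layout.
#'
#' @inheritParams cohort_models
#' @param cohorts Cohort labels (default all nine).
#' @param out_dir Optional directory: writes `cea.csv` and per-cohort
#'   per-strategy `trace_<cohort>_<strategy>.csv` files.
#' @return A data frame with one row per cohort x strategy: `cohort`,
#'   `strategy`, `cost`, `qaly`, `pfs_imputed`, `icer_tmz_vs_rt`,
#'   `icer_tmz_vs_nt`, `icer_nt_vs_rt` (ICERs repeated on each row of the
#'   cohort).
#' @export
run_base_case <- function(config = default_config(), cohorts = gbm_cohorts(),
                          out_dir = NULL) {
  unknown <- setdiff(cohorts, gbm_cohorts())
  if (length(unknown) > 0)
    stop("unknown cohort(s) ", paste(unknown, collapse = ", "),
         "; valid: ", paste(gbm_cohorts(), collapse = ", "))
  rows <- list()
  for (cohort in cohorts) {
    models <- cohort_models(config, cohort)
    evals <- lapply(gbm_strategies(), function(s)
      evaluate_strategy(config, cohort, s, models))
    names(evals) <- gbm_strategies()
    oc <- lapply(evals, `[[`, "outcome")
    inc_tr <- incremental(oc$`RT+TMZ`, oc$RT)
    inc_tn <- incremental(oc$`RT+TMZ`, oc$`RT+NT`)
    inc_nr <- incremental(oc$`RT+NT`, oc$RT)
    for (s in gbm_strategies()) {
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cohort, strategy = s,
        cost = oc[[s]]$cost, qaly = oc[[s]]$qaly,
        pfs_imputed = evals[[s]]$pfs_imputed,
        icer_tmz_vs_rt = inc_tr$icer, icer_tmz_vs_nt = inc_tn$icer,
        icer_nt_vs_rt = inc_nr$icer)
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (s in gbm_strategies())
        utils::write.csv(evals[[s]]$trace,
                         file.path(out_dir, sprintf("trace_%s_%s.csv", cohort,
                                                    gsub("[+]", "_", s))),
                         row.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "cea.csv"), row.names = FALSE)
  out
}

#' Validate model medians against trial confidence intervals
#'
#' For every trial median in the configuration, computes the model median
#' from the corresponding cohort trace (linear interpolation of the 0.5
#' crossing) and checks it against the trial's 95% CI.
#'
#' @inheritParams cohort_models
#' @param out_file Optional CSV path for the validation table.
#' @return A data frame: `cohort`, `arm`, `endpoint`, `trial_median`,
#'   `ci_low`, `ci_high`, `model_median`, `pass`, `margin`.
#' @export
run_validation <- function(config = default_config(), out_file = NULL) {
  tm <- config$trial_medians
  traces <- new.env(parent = emptyenv())
  get_trace <- function(cohort, arm) {
    key <- paste(cohort, arm)
    if (is.null(traces[[key]])) {
      m <- cohort_models(config, cohort)[[arm]]
      traces[[key]] <- run_cohort(m$pfs, m$os, config$settings$horizon)
    }
    traces[[key]]
  }
  rows <- lapply(seq_len(nrow(tm)), function(i) {
    r <- tm[i, ]
    tr <- get_trace(r$cohort, r$arm)
    mm <- model_median_from_trace(tr, r$endpoint)
    v <- validate_against_trial(mm, trial_median(r$cohort, r$arm, r$endpoint,
                                                 r$median, r$ci_low, r$ci_high))
    data.frame(cohort = r$cohort, arm = r$arm, endpoint = r$endpoint,
               trial_median = r$median, ci_low = r$ci_low, ci_high = r$ci_high,
               model_median = mm, pass = v$pass, margin = v$margin)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_file)) utils::write.csv(out, out_file, row.names = FALSE)
  out
}
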