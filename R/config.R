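#' Default model configuration
#'
#' Assembles the full analysis configuration: unit costs, utilities, the
#' Weibull parameter table (the calibrated synthetic table unless a real
#' one is supplied), trial medians for validation, the nitrosourea hazard
#' ratio, second-line and adverse-event conventions, the typical patient
#' profile, and analysis settings (cycle length 1 month, 60-cycle horizon,
#' no discounting, willingness-to-pay thresholds of $11,034 and $38,376
#' per QALY, CNY/USD exchange rate 6.50).
#'
#' @param params Optional S1-shaped Weibull parameter data frame (columns
#'   `cohort, arm, endpoint, shape, scale, se_shape, se_scale, corr`);
#'   defaults to [calibrated_parameter_table()].
#' @param costs A [cost_table()].
#' @param utilities A [utility_table()].
#' @param profile A [patient_profile()].
#' @param ... Named overrides for `settings` entries.
#' @return An object of class `gbm_config`.
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' @export
default_config <- function(params = calibrated_parameter_table(),
                           costs = cost_table(),
                           utilities = utility_table(),
                           profile = patient_profile(), ...) {
  tm <- utils::read.csv(system.file("extdata", "trial_medians.csv",
                                    package = "gbmcea"),
                        stringsAsFactors = FALSE)
  reference <- utils::read.csv(system.file("extdata", "base_case_reference.csv",
                                           package = "gbmcea"),
                               stringsAsFactors = FALSE)
  settings <- list(horizon = 60, cycle_length = 1, discount_rate = 0,
                   wtp_china = 11034, wtp_shanghai = 38376,
                   exchange_rate_cny_per_usd = 6.5,
                   capsule_rounding = "up", follow_up_policy = "all_pf",
                   include_initial_surgery = FALSE,
                   bsa_range = c(1.61, 1.83))
  over <- list(...)
  for (nm in names(over)) settings[[nm]] <- over[[nm]]
  cfg <- list(
    params = validate_parameter_table(params),
    costs = costs,
    utilities = utilities,
    profile = profile,
    trial_medians = tm,
    reference = reference,
    hr_nt = list(os = list(mean = 0.85, low = 0.78, high = 0.91),
                 pfs = list(mean = 0.85, low = 0.78, high = 0.91)),
    sae_probs = list(hematologic = list(mean = 0.12, low = 0.08, high = 0.16),
                     infection = list(mean = 0.03, low = 0.01, high = 0.05),
                     gastrointestinal = list(mean = 0.03, low = 0.01, high = 0.05)),
    second_line_mix = list(chemo = list(mean = 0.40, low = 0.30, high = 0.50),
                           surgery = list(mean = 0.10, low = 0.05, high = 0.15),
                           bsc = list(mean = 0.50, low = 0.40, high = 0.60)),
    surgery_mix = c(operation = 0.84, biopsy = 0.16),
    settings = settings)
  class(cfg) <- "gbm_config"
  cfg
}

#' Load a configuration from a YAML (or JSON) file
#'
#' The file may override any subset of the defaults: a `settings` mapping,
#' `costs`/`utilities` item overrides, `hr_nt`, and a `parameter_table`
#' path pointing to an S1-shaped CSV (relative paths are resolved against
#' the config file's directory). Omitted entries keep their
#' [default_config()] values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `gbm_config` object.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  params <- if (!is.null(raw$parameter_table)) {
    p <- raw$parameter_table
    if (!file.exists(p)) p <- file.path(dirname(path), raw$parameter_table)
    read_parameter_table(p)
  } else calibrated_parameter_table()
  costs <- do.call(cost_table, raw$costs %||% list())
  utilities <- do.call(utility_table, raw$utilities %||% list())
  profile <- do.call(patient_profile, raw$profile %||% list())
  cfg <- do.call(default_config,
                 c(list(params = params, costs = costs,
                        utilities = utilities, profile = profile),
                   raw$settings %||% list()))
  if (!is.null(raw$hr_nt)) cfg$hr_nt <- utils::modifyList(cfg$hr_nt, raw$hr_nt)
  if (!is.null(raw$sae_probs))
    cfg$sae_probs <- utils::modifyList(cfg$sae_probs, raw$sae_probs)
  if (!is.null(raw$second_line_mix))
    cfg$second_line_mix <- utils::modifyList(cfg$second_line_mix,
                                             raw$second_line_mix)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_parameter_table <- function(df) {
  need <- c("cohort", "arm", "endpoint", "shape", "scale")
  if (!all(need %in% names(df)))
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  for (nm in c("se_shape", "se_scale", "corr"))
    if (is.null(df[[nm]])) df[[nm]] <- 0
  if (is.null(df$imputed)) df$imputed <- FALSE
  if (is.null(df$synthetic)) df$synthetic <- FALSE
  if (any(df$shape <= 0) || any(df$scale <= 0))
    stop("shape and scale must be positive")
  if (!all(df$endpoint %in% c("OS", "PFS")))
    stop("endpoint must be OS or PFS")
  df
}

#' Read an S1-shaped Weibull parameter table
#'
#' CSV with columns `cohort, arm, endpoint, shape, scale[, se_shape,
#' se_scale, corr]`. The `parameterization` flag handles tables whose
#' "scale" is a characteristic life rather than a rate (converted on
#' input).
#'
#' @param path CSV path.
#' @param parameterization `"rate"` (default) or `"characteristic_life"`.
#' @return A validated parameter data frame.
#' @export
read_parameter_table <- function(path,
                                 parameterization = c("rate", "characteristic_life")) {
  parameterization <- match.arg(parameterization)
  df <- validate_parameter_table(utils::read.csv(path, stringsAsFactors = FALSE))
  if (parameterization == "characteristic_life") {
    for (i in seq_len(nrow(df))) {
      p <- weibull_params(df$shape[i], df$scale[i], df$se_shape[i],
                          df$se_scale[i], df$corr[i],
                          parameterization = "characteristic_life")
      df$scale[i] <- p$scale; df$se_scale[i] <- p$se_scale
    }
  }
  df
}

# fetch one row of the parameter table as weibull_params (NULL if absent)
param_row <- function(params, cohort, arm, endpoint) {
  i <- which(params$cohort == cohort & params$arm == arm &
               params$endpoint == endpoint)
  if (length(i) == 0L) return(NULL)
  if (length(i) > 1L) stop("duplicate parameter rows for ",
                           paste(cohort, arm, endpoint))
  weibull_params(params$shape[i], params$scale[i], params$se_shape[i],
                 params$se_scale[i], params$corr[i])
}

#' Read Kaplan-Meier coordinates from CSV
#'
#' Expects columns `time_months`, `survival` and optionally `n_risk`.
#'
#' @param path CSV path.
#' @return A [km_curve()] object.
#' @export
read_km_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_months", "survival") %in% names(df)))
    stop("KM CSV needs columns time_months, survival")
  km_curve(df$time_months, df$survival, df$n_risk)
}

#' Cohort and strategy labels used by the analysis
#'
#' @return Character vectors.
#' @export
gbm_cohorts <- function() c("overall", "mgmt_methylated", "mgmt_unmethylated",
                            "complete_resection", "partial_resection",
                            "biopsy_only", "age_lt50", "age_50_60", "age_gt60")

#' @rdname gbm_cohorts
#' @export
gbm_strategies <- function() c("RT", "RT+NT", "RT+TMZ")
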