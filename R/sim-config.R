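#' Configuration for the synthetic record generator
#'
#' Defines a cohort of patients with longitudinal primary-care-style records
#' and a known causal structure: treatment initiation is confounded by
#' measured covariates, exposure is sustained or discontinued at 3-month
#' intervals, and the study outcome and death are drawn from discrete-time
#' hazards in which current exposure multiplies the outcome odds by
#' `true_effect`.
#'
#' The defaults describe the study conditions used throughout the package's
#' own analyses: an index-condition cohort registered in mid-life and followed
#' for decades, a per-interval treatment-initiation probability of a few
#' percent that rises with disease severity, a baseline outcome hazard of
#' 0.4% per 3-month interval (about 1.6% per year) and a comparable death
#' hazard. See the methods vignette for the rationale behind each value.
#'
#' @param n_patients number of patients to simulate (>= 1).
#' @param seed integer RNG seed; identical configurations produce
#'   byte-identical datasets.
#' @param birth_date_range `Date` vector of length 2; birth dates are drawn
#'   uniformly on this interval.
#' @param registration_window list with `start_age` (years, length 2) and
#'   `duration_years` (length 2); registration start is at a uniform age in
#'   `start_age` and lasts a uniform number of years in `duration_years`
#'   (administrative censoring at registration end).
#' @param covariate_spec list of covariate definitions, each a list with
#'   `name`, `type` (`"binary"`, `"continuous"` or `"categorical"`) and its
#'   marginal distribution: `prob` for binary, `mean`/`sd` for continuous,
#'   `levels`/`probs` for categorical. Covariates are sampled once at
#'   registration (time-fixed).
#' @param initiation_model list with `intercept` and named `coef` vector
#'   giving the per-interval treatment-initiation log-odds as a linear
#'   function of covariates. Coefficients may only reference binary or
#'   continuous covariates. Use `intercept = -Inf` to forbid initiation.
#' @param discontinuation_prob probability of stopping treatment at each
#'   exposed interval; a stopped patient may re-initiate later.
#' @param outcome_hazard list with `base` (scalar per-interval discrete
#'   hazard, or a function of the 0-based interval index) and optional named
#'   `coef` vector of covariate log-odds effects on the outcome.
#' @param true_effect multiplicative effect of current-interval exposure on
#'   the outcome odds (1 = null; > 0).
#' @param death_hazard list with `base` (scalar or function of interval
#'   index), optional `exposure_or` (odds multiplier of current exposure on
#'   death, default 1) and optional named `coef` vector.
#' @param condition_codes named list of abstract code strings:
#'   `index_condition` (cohort-defining diagnosis), `outcome_condition`
#'   (outcome diagnosis code), `study_drug` (drug class under study) and
#'   `confirm_drug` (confirmatory prescription class emitted with each
#'   outcome, so `"code_and_two_rx"` outcome definitions are ascertainable).
#' @param interval_length_days length of the simulation interval in days;
#'   91 days is about 3 months, so four intervals approximate one year.
#' @param index_condition_prob probability that a patient carries the index
#'   condition (diagnosed at registration start).
#'
#' @return an object of class `sim_config`.
#' @seealso [generate_population()], [true_marginal_risk()]
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       birth_date_range = as.Date(c("1935-01-01", "1965-12-31")),
                       registration_window = list(start_age = c(40, 55),
                                                  duration_years = c(10, 45)),
                       covariate_spec = default_covariate_spec(),
                       initiation_model = list(
                         intercept = -4.0,
                         coef = c(severity = 0.8, biomarker = 0.3, comorbidity = 0.4)),
                       discontinuation_prob = 0.08,
                       outcome_hazard = list(
                         base = 0.004,
                         coef = c(severity = 0.5, biomarker = 0.2)),
                       true_effect = 1.0,
                       death_hazard = list(
                         base = 0.003,
                         exposure_or = 1.0,
                         coef = c(comorbidity = 0.5)),
                       condition_codes = list(index_condition = "cond_index",
                                              outcome_condition = "cond_outcome",
                                              study_drug = "rx_study",
                                              confirm_drug = "rx_confirm"),
                       interval_length_days = 91L,
                       index_condition_prob = 1.0) {
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              birth_date_range = as.Date(birth_date_range),
              registration_window = registration_window,
              covariate_spec = covariate_spec,
              initiation_model = initiation_model,
              discontinuation_prob = discontinuation_prob,
              outcome_hazard = outcome_hazard,
              true_effect = true_effect,
              death_hazard = death_hazard,
              condition_codes = condition_codes,
              interval_length_days = as.integer(interval_length_days),
              index_condition_prob = index_condition_prob)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients, seed", x$seed, "\n")
  cat("  covariates:", paste(vapply(x$covariate_spec, `[[`, "", "name"),
                             collapse = ", "), "\n")
  cat("  true exposure odds ratio:", x$true_effect, "\n")
  invisible(x)
}

default_covariate_spec <- function() {
  list(
    list(name = "severity",    type = "binary",     prob = 0.35),
    list(name = "biomarker",   type = "continuous", mean = 0, sd = 1),
    list(name = "comorbidity", type = "binary",     prob = 0.25)
  )
}

sim_config_error <- function(field, msg) {
  stop(sprintf("invalid sim_config field `%s`: %s", field, msg), call. = FALSE)
}

check_hazard_field <- function(h, field) {
  if (is.function(h$base)) {
    probe <- h$base(0:3)
    if (any(!is.finite(probe)) || any(probe < 0) || any(probe > 1))
      sim_config_error(field, "base hazard function must return values in [0,1]")
  } else if (!is.numeric(h$base) || length(h$base) != 1L ||
             h$base < 0 || h$base > 1) {
    sim_config_error(field, "base must be a probability in [0,1] or a function")
  }
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      cfg$n_patients < 1)
    sim_config_error("n_patients", "must be a single number >= 1")
  if (length(cfg$birth_date_range) != 2L ||
      cfg$birth_date_range[1] > cfg$birth_date_range[2])
    sim_config_error("birth_date_range", "must be an increasing date pair")
  if (!is.numeric(cfg$true_effect) || cfg$true_effect <= 0)
    sim_config_error("true_effect", "must be > 0")
  if (cfg$discontinuation_prob < 0 || cfg$discontinuation_prob > 1)
    sim_config_error("discontinuation_prob", "must be in [0,1]")
  if (cfg$index_condition_prob < 0 || cfg$index_condition_prob > 1)
    sim_config_error("index_condition_prob", "must be in [0,1]")
  if (cfg$interval_length_days < 1)
    sim_config_error("interval_length_days", "must be >= 1")
  check_hazard_field(cfg$outcome_hazard, "outcome_hazard")
  check_hazard_field(cfg$death_hazard, "death_hazard")
  nm <- vapply(cfg$covariate_spec, function(s) s$name %||% "", "")
  if (anyDuplicated(nm) || any(nm == ""))
    sim_config_error("covariate_spec", "covariate names must be unique and nonempty")
  types <- vapply(cfg$covariate_spec, `[[`, "", "type")
  if (!all(types %in% c("binary", "continuous", "categorical")))
    sim_config_error("covariate_spec", "type must be binary, continuous or categorical")
  model_coefs <- c(names(cfg$initiation_model$coef),
                   names(cfg$outcome_hazard$coef),
                   names(cfg$death_hazard$coef))
  ok_names <- nm[types %in% c("binary", "continuous")]
  bad <- setdiff(model_coefs, ok_names)
  if (length(bad))
    sim_config_error("initiation_model/outcome_hazard/death_hazard",
                     paste("coefficients reference unknown or categorical covariates:",
                           paste(bad, collapse = ", ")))
  needed <- c("index_condition", "outcome_condition", "study_drug", "confirm_drug")
  if (!all(needed %in% names(cfg$condition_codes)))
    sim_config_error("condition_codes",
                     paste("must name", paste(needed, collapse = ", ")))
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
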