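#' Generate a synthetic longitudinal record dataset
#'
#' Simulates a cohort with the causal structure declared in a [sim_config()]:
#' per 3-month interval of registered life, an untreated patient initiates
#' the study drug with probability given by the confounded initiation model,
#' a treated patient discontinues with `discontinuation_prob`, every exposed
#' interval emits one study-drug prescription at the interval start, and the
#' study outcome and death are drawn from discrete hazards in which current
#' exposure multiplies the outcome odds by `true_effect`. Follow-up ends at
#' death or administrative censoring (registration end). The first outcome
#' event emits an outcome diagnosis plus two confirmatory prescriptions on
#' distinct dates, so code-plus-two-prescription outcome definitions are
#' ascertainable downstream.
#'
#' @param config a [sim_config()].
#' @return an object of class `ehr_dataset`: a list of four
#'   `data.table`s (`patients`, `diagnoses`, `prescriptions`, `covariates`)
#'   plus `provenance` metadata recording the seed.
#' @examples
#' ehr <- generate_population(sim_config(n_patients = 50, seed = 7))
#' names(ehr)
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  ilen <- config$interval_length_days

  birth <- config$birth_date_range[1] +
    floor(stats::runif(n) *
            (as.numeric(diff(config$birth_date_range)) + 1))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  rw <- config$registration_window
  start_age <- stats::runif(n, rw$start_age[1], rw$start_age[2])
  dur_yrs <- stats::runif(n, rw$duration_years[1], rw$duration_years[2])
  reg_start <- birth + round(365.25 * start_age)
  reg_end <- reg_start + round(365.25 * dur_yrs)
  has_index <- stats::runif(n) < config$index_condition_prob

  covs <- draw_covariates(config$covariate_spec, n)
  lin_init <- linear_predictor(config$initiation_model$coef, covs) +
    config$initiation_model$intercept
  lin_out <- linear_predictor(config$outcome_hazard$coef, covs)
  lin_death <- linear_predictor(config$death_hazard$coef, covs)
  exp_or_death <- config$death_hazard$exposure_or %||% 1.0
  out_base <- make_hazard_fun(config$outcome_hazard$base)
  death_base <- make_hazard_fun(config$death_hazard$base)

  max_k <- ceiling(max(as.numeric(reg_end - reg_start)) / ilen)

  alive <- rep(TRUE, n)
  exposed <- rep(FALSE, n)
  had_event <- rep(FALSE, n)
  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  event_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")

  rx_pid <- vector("list", max_k)
  rx_date <- vector("list", max_k)

  for (k in seq_len(max_k) - 1L) {
    date_k <- reg_start + k * ilen
    active <- which(alive & date_k < reg_end)
    if (!length(active)) break

    # exposure state transition, then prescriptions for exposed intervals
    was <- exposed[active]
    u <- stats::runif(length(active))
    p_tr <- ifelse(was, 1 - config$discontinuation_prob, plogis_safe(lin_init[active]))
    exposed[active] <- u < p_tr
    on_now <- active[exposed[active]]
    if (length(on_now)) {
      rx_pid[[k + 1L]] <- on_now
      rx_date[[k + 1L]] <- reg_start[on_now] + k * ilen
    }

    # first outcome event (patients stay under observation afterwards)
    at_risk <- active[!had_event[active]]
    if (length(at_risk)) {
      h <- plogis_safe(stats::qlogis(pmin(pmax(out_base(k), 1e-12), 1 - 1e-12)) +
                         lin_out[at_risk] +
                         exposed[at_risk] * log(config$true_effect))
      hit <- at_risk[stats::runif(length(at_risk)) < h]
      if (length(hit)) {
        had_event[hit] <- TRUE
        event_date[hit] <- reg_start[hit] + k * ilen + 45L
      }
    }

    # death terminates the record
    hd <- plogis_safe(stats::qlogis(pmin(pmax(death_base(k), 1e-12), 1 - 1e-12)) +
                        lin_death[active] +
                        exposed[active] * log(exp_or_death))
    dead_now <- active[stats::runif(length(active)) < hd]
    if (length(dead_now)) {
      alive[dead_now] <- FALSE
      death_date[dead_now] <- reg_start[dead_now] + k * ilen + 80L
    }
  }

  codes <- config$condition_codes
  patients <- data.table::data.table(
    patient_id = seq_len(n), sex = sex, birth_date = birth,
    reg_start = reg_start, reg_end = pmin_date(reg_end, death_date),
    death_date = death_date)

  diag_list <- list(
    data.table::data.table(patient_id = which(has_index),
                           event_date = reg_start[has_index],
                           condition_code = codes$index_condition))
  ev <- which(had_event)
  if (length(ev)) {
    diag_list[[2]] <- data.table::data.table(
      patient_id = ev, event_date = event_date[ev],
      condition_code = codes$outcome_condition)
  }
  diagnoses <- data.table::rbindlist(diag_list)
  data.table::setorder(diagnoses, patient_id, event_date)

  rx_ids <- unlist(rx_pid, use.names = FALSE) %||% integer(0)
  rx_study <- data.table::data.table(
    patient_id = rx_ids,
    issue_date = as.Date(unlist(lapply(rx_date, as.integer), use.names = FALSE) %||%
                           integer(0), origin = "1970-01-01"),
    drug_class = rep(codes$study_drug, length(rx_ids)))
  rx_confirm <- if (length(ev)) {
    data.table::data.table(
      patient_id = rep(ev, 2L),
      issue_date = c(event_date[ev], event_date[ev] + 1L),
      drug_class = codes$confirm_drug)
  } else {
    data.table::data.table(patient_id = integer(0),
                           issue_date = as.Date(integer(0), origin = "1970-01-01"),
                           drug_class = character(0))
  }
  prescriptions <- data.table::rbindlist(list(rx_study, rx_confirm))
  data.table::setorder(prescriptions, patient_id, issue_date, drug_class)

  cov_tab <- covariate_long_table(covs, config$covariate_spec, reg_start)

  out <- structure(
    list(patients = patients, diagnoses = diagnoses,
         prescriptions = prescriptions, covariates = cov_tab,
         provenance = list(generator = "seqtte::generate_population",
                           seed = config$seed,
                           n_patients = n,
                           interval_length_days = ilen,
                           true_effect = config$true_effect)),
    class = "ehr_dataset")
  validate_ehr(out)
  out
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>", nrow(x$patients), "patients,",
      nrow(x$diagnoses), "diagnoses,",
      nrow(x$prescriptions), "prescriptions,",
      nrow(x$covariates), "covariate records\n")
  invisible(x)
}

#' Check the structural invariants of a record dataset
#'
#' Verifies that every event date lies within the patient's lifespan, that
#' event-table patient ids are a subset of the patient table, and that each
#' registration window is nonempty. Called automatically by
#' [generate_population()] and [read_ehr_dataset()].
#'
#' @param data an `ehr_dataset`.
#' @return the dataset, invisibly; errors on violation.
#' @export
validate_ehr <- function(data) {
  p <- data$patients
  stopifnot(is.data.frame(p), all(c("patient_id", "birth_date", "reg_start",
                                    "reg_end") %in% names(p)))
  if (any(p$reg_start >= p$reg_end))
    stop("registration start must precede registration end for every patient")
  ids <- p$patient_id
  for (tab in c("diagnoses", "prescriptions", "covariates")) {
    t <- data[[tab]]
    if (!all(t$patient_id %in% ids))
      stop(sprintf("%s refers to patient ids absent from the patient table", tab))
  }
  dcol <- list(diagnoses = "event_date", prescriptions = "issue_date",
               covariates = "measurement_date")
  death <- p$death_date[match(ids, p$patient_id)]
  for (tab in names(dcol)) {
    t <- data[[tab]]
    if (!nrow(t)) next
    i <- match(t$patient_id, p$patient_id)
    d <- t[[dcol[[tab]]]]
    if (any(d < p$birth_date[i]))
      stop(sprintf("%s contains dates before birth", tab))
    dd <- p$death_date[i]
    if (any(!is.na(dd) & d > dd))
      stop(sprintf("%s contains dates after death", tab))
  }
  invisible(data)
}

# -- internal helpers ---------------------------------------------------------

plogis_safe <- function(x) {
  p <- stats::plogis(x)
  p[is.nan(p)] <- 0  # intercept -Inf encodes "initiation impossible"
  p
}

pmin_date <- function(a, b) {
  out <- a
  repl <- !is.na(b) & b < a
  out[repl] <- b[repl]
  out
}

make_hazard_fun <- function(base) {
  if (is.function(base)) base else function(k) rep(base, length(k))[seq_along(k)]
}

draw_covariates <- function(spec, n) {
  out <- list()
  for (s in spec) {
    out[[s$name]] <- switch(
      s$type,
      binary = as.numeric(stats::runif(n) < s$prob),
      continuous = stats::rnorm(n, s$mean %||% 0, s$sd %||% 1),
      categorical = sample(s$levels, n, replace = TRUE,
                           prob = s$probs %||% NULL))
  }
  out
}

linear_predictor <- function(coef, covs) {
  n <- length(covs[[1]]) %||% 0L
  if (is.null(coef) || !length(coef)) return(numeric(max(n, 0L)))
  lp <- numeric(n)
  for (nm in names(coef)) lp <- lp + coef[[nm]] * covs[[nm]]
  lp
}

covariate_long_table <- function(covs, spec, dates) {
  n <- length(dates)
  parts <- lapply(spec, function(s) {
    data.table::data.table(patient_id = seq_len(n), measurement_date = dates,
                           name = s$name, value = as.character(covs[[s$name]]))
  })
  tab <- data.table::rbindlist(parts)
  data.table::setorder(tab, patient_id, name)
  tab
}
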