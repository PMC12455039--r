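#' Eligibility rules for the sequential trials
#'
#' Encodes the new-user design: patients must carry the index condition, be
#' inside the age window, be actively registered and alive at the index
#' date, have no history of any exclusion condition or exclusion drug class
#' on or before the index date, and have no study-drug prescription during
#' the washout window before the index date. Prescriptions dated exactly on
#' the index date are treated as post-baseline initiation events, not
#' washout violations, so an initiation cannot disqualify itself.
#'
#' @param index_condition character vector of codes defining the cohort
#'   condition; a diagnosis on or before the index date is required.
#' @param age_min,age_max inclusive age window in whole years.
#' @param exclusion_conditions codes whose presence at any time up to the
#'   index date excludes the patient (e.g. prevalent outcome disease).
#' @param exclusion_drug_classes drug classes whose prescription at any time
#'   up to the index date excludes the patient.
#' @param washout_drug_class the study-drug class subject to washout.
#' @param washout_days length of the washout window (default 365): a
#'   study-drug prescription strictly inside `(index - washout_days, index)`
#'   excludes the patient.
#' @param min_history_days minimum days between registration start and the
#'   index date (0 by default; 5 years in the record-history sensitivity).
#' @param allow_reinitiators when `FALSE`, any study-drug prescription
#'   before the index date excludes the patient, not only recent ones.
#' @return an object of class `eligibility_spec`.
#' @export
eligibility_spec <- function(index_condition,
                             age_min = 50, age_max = 84,
                             exclusion_conditions = character(0),
                             exclusion_drug_classes = character(0),
                             washout_drug_class,
                             washout_days = 365L,
                             min_history_days = 0L,
                             allow_reinitiators = TRUE) {
  if (washout_days < 0) stop("washout_days must be >= 0")
  if (age_min >= age_max) stop("age_min must be below age_max")
  structure(list(index_condition = index_condition,
                 age_min = age_min, age_max = age_max,
                 exclusion_conditions = exclusion_conditions,
                 exclusion_drug_classes = exclusion_drug_classes,
                 washout_drug_class = washout_drug_class,
                 washout_days = as.integer(washout_days),
                 min_history_days = as.integer(min_history_days),
                 allow_reinitiators = isTRUE(allow_reinitiators)),
            class = "eligibility_spec")
}

#' Assess eligibility at one trial time point
#'
#' Applies an [eligibility_spec()] to every patient at the per-patient index
#' date implied by a trial grid point (the date the patient attains that
#' exact age, or the calendar date itself). Returns the eligible patients
#' with their index dates; an empty result is valid.
#'
#' @param data an `ehr_dataset`.
#' @param spec an [eligibility_spec()].
#' @param grid a [trial_grid()].
#' @param trial trial index within the grid.
#' @return `data.table` with columns `patient_id` and `index_date`.
#' @export
assess_eligibility <- function(data, spec, grid, trial) {
  p <- data$patients
  if (!nrow(p)) {
    return(data.table::data.table(patient_id = integer(0),
                                  index_date = as.Date(integer(0),
                                                       origin = "1970-01-01")))
  }
  idx <- index_dates_for(grid, trial, p$birth_date)

  ok <- idx >= p$reg_start & idx < p$reg_end &
    (is.na(p$death_date) | idx < p$death_date) &
    as.numeric(idx - p$reg_start) >= spec$min_history_days
  age <- age_years_at(p$birth_date, idx)
  ok <- ok & age >= spec$age_min & age < spec$age_max + 1

  dg <- data$diagnoses
  rx <- data$prescriptions
  idx_by_id <- idx[match(dg$patient_id, p$patient_id)]
  has_index_cond <- unique(dg$patient_id[
    dg$condition_code %in% spec$index_condition & dg$event_date <= idx_by_id])
  ok <- ok & p$patient_id %in% has_index_cond

  if (length(spec$exclusion_conditions)) {
    excl <- unique(dg$patient_id[
      dg$condition_code %in% spec$exclusion_conditions &
        dg$event_date <= idx_by_id])
    ok <- ok & !(p$patient_id %in% excl)
  }
  idx_by_rx <- idx[match(rx$patient_id, p$patient_id)]
  if (length(spec$exclusion_drug_classes)) {
    excl <- unique(rx$patient_id[
      rx$drug_class %in% spec$exclusion_drug_classes &
        rx$issue_date <= idx_by_rx])
    ok <- ok & !(p$patient_id %in% excl)
  }

  is_study <- rx$drug_class %in% spec$washout_drug_class
  if (spec$allow_reinitiators) {
    viol <- is_study & rx$issue_date < idx_by_rx &
      rx$issue_date > idx_by_rx - spec$washout_days
  } else {
    viol <- is_study & rx$issue_date < idx_by_rx
  }
  ok <- ok & !(p$patient_id %in% unique(rx$patient_id[viol]))

  data.table::data.table(patient_id = p$patient_id[ok], index_date = idx[ok])
}
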