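#' Assign treatment arms and baseline covariates at trial entry
#'
#' Builds one patient-trial row per eligible (patient, trial) pair. The arm
#' is fixed at baseline: a patient is an `initiator` if and only if at
#' least one study-drug prescription falls in the first 3 months of
#' follow-up, `[index, index + interval_days)`; later initiation does not
#' change the arm (it is handled by the per-protocol dose model, not the
#' intention-to-treat arm). Baseline covariates are the most recent
#' measurement on or before the index date within each covariate's lookback
#' window (unlimited by default; e.g. 365 days for hospitalisation counts,
#' 180 days for concurrent medications).
#'
#' @param eligible table of `patient_id`, `index_date` pairs for one trial
#'   (from [assess_eligibility()]), or a combined table with a `trial_id`
#'   column for several trials.
#' @param data an `ehr_dataset`.
#' @param study_drug drug class defining initiation.
#' @param trial_id trial identifier recorded in the output (ignored when
#'   `eligible` already carries a `trial_id` column).
#' @param covariate_lookback named list or vector of lookback windows in
#'   days per covariate name; unnamed covariates use `Inf` (ever before
#'   baseline).
#' @param interval_days length of the arm-assignment window (default 91).
#' @return `data.table` of patient-trials: `patient_id`, `trial_id`,
#'   `index_date`, `arm` plus one column per covariate (numeric where the
#'   recorded values parse as numbers, character otherwise) and `sex` from
#'   the patient table.
#' @export
assign_arms <- function(eligible, data, study_drug, trial_id = 1L,
                        covariate_lookback = list(), interval_days = 91L) {
  el <- data.table::as.data.table(eligible)
  if (!nrow(el)) {
    return(data.table::data.table(patient_id = integer(0), trial_id = integer(0),
                                  index_date = as.Date(integer(0),
                                                       origin = "1970-01-01"),
                                  arm = character(0)))
  }
  if (!"trial_id" %in% names(el)) el$trial_id <- as.integer(trial_id)
  el$pt_id <- seq_len(nrow(el))

  rx <- data$prescriptions
  rx <- rx[rx$drug_class %in% study_drug,
           c("patient_id", "issue_date"), with = FALSE]
  j <- merge(el[, c("pt_id", "patient_id", "index_date"), with = FALSE], rx,
             by = "patient_id", allow.cartesian = TRUE)
  init_ids <- unique(j$pt_id[j$issue_date >= j$index_date &
                               j$issue_date < j$index_date + interval_days])
  el$arm <- ifelse(el$pt_id %in% init_ids, "initiator", "non-initiator")

  cv <- data$covariates
  if (nrow(cv)) {
    jc <- merge(el[, c("pt_id", "patient_id", "index_date"), with = FALSE],
                cv, by = "patient_id", allow.cartesian = TRUE)
    lb <- vapply(unique(cv$name), function(nm) {
      v <- covariate_lookback[[nm]]
      if (is.null(v)) Inf else as.numeric(v)
    }, 0)
    jc <- jc[jc$measurement_date <= jc$index_date &
               as.numeric(jc$index_date - jc$measurement_date) < lb[jc$name], ]
    data.table::setorder(jc, pt_id, name, measurement_date)
    last <- jc[, list(value = value[.N]), by = c("pt_id", "name")]
    wide <- data.table::dcast(last, pt_id ~ name, value.var = "value")
    for (nm in setdiff(names(wide), "pt_id")) {
      v <- wide[[nm]]
      num <- suppressWarnings(as.numeric(v))
      if (!any(is.na(num) & !is.na(v))) wide[[nm]] <- num
    }
    el <- merge(el, wide, by = "pt_id", all.x = TRUE)
  }
  el <- merge(el, data$patients[, c("patient_id", "sex"), with = FALSE],
              by = "patient_id", sort = FALSE)
  data.table::setorder(el, trial_id, patient_id)
  el$pt_id <- seq_len(nrow(el))
  data.table::setcolorder(el, c("pt_id", "patient_id", "trial_id",
                                "index_date", "arm", "sex"))
  el[]
}

utils::globalVariables(c("pt_id", "value", ".N", "name"))
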