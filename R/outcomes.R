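#' Outcome definition
#'
#' Describes how an outcome is ascertained from the record tables and how
#' death is handled during follow-up.
#'
#' Definitions: `"code_and_two_rx"` requires a diagnosis code from `codes`
#' plus at least two prescriptions of a confirmatory drug class on distinct
#' dates at any time (the primary neurodegenerative-outcome convention);
#' `"gp_code"`, `"hospital_code"`, `"gp_or_hospital"` and `"plain_code"` all
#' ascertain the earliest diagnosis whose code lies in `codes` (the code set
#' distinguishes the record source, since codes are abstract strings here).
#'
#' @param name outcome label used in reports.
#' @param definition one of `"code_and_two_rx"`, `"gp_code"`,
#'   `"hospital_code"`, `"gp_or_hospital"`, `"plain_code"`.
#' @param codes character vector of qualifying diagnosis codes.
#' @param confirm_rx drug classes of the confirmatory prescriptions
#'   (required, nonempty, for `"code_and_two_rx"`).
#' @param history_exclusion drop patient-trials with the outcome on or
#'   before the index date before expansion (used for neuropsychiatric and
#'   sleep outcomes).
#' @param death_handling `"censor"` (default), `"competing_event"` (death is
#'   recorded as a terminal competing event) or `"composite"` (death counts
#'   as the outcome).
#' @param lead_time_years shift the ascertained onset date this many years
#'   before the diagnosis date (diagnostic-latency sensitivity; default 0).
#' @return an object of class `outcome_spec`.
#' @export
outcome_spec <- function(name, definition = "code_and_two_rx",
                         codes, confirm_rx = character(0),
                         history_exclusion = FALSE,
                         death_handling = c("censor", "competing_event", "composite"),
                         lead_time_years = 0) {
  defs <- c("code_and_two_rx", "gp_code", "hospital_code",
            "gp_or_hospital", "plain_code")
  if (!definition %in% defs)
    stop("unknown outcome definition: ", definition)
  if (definition == "code_and_two_rx" && !length(confirm_rx))
    stop("code_and_two_rx requires a nonempty confirm_rx set")
  structure(list(name = name, definition = definition, codes = codes,
                 confirm_rx = confirm_rx,
                 history_exclusion = isTRUE(history_exclusion),
                 death_handling = match.arg(death_handling),
                 lead_time_years = lead_time_years),
            class = "outcome_spec")
}

#' Ascertain outcome onset dates
#'
#' Returns the first qualifying outcome date per patient under an
#' [outcome_spec()]. For `"code_and_two_rx"` this is the earliest diagnosis
#' in the code set for patients holding at least two confirmatory
#' prescriptions on distinct dates (at any time); for the code-based
#' definitions it is the earliest diagnosis in the code set. A configured
#' lead time shifts the returned date earlier by whole years.
#'
#' @param data an `ehr_dataset`.
#' @param spec an [outcome_spec()].
#' @param patient_ids optional subset of patients to consider.
#' @return `data.table` with `patient_id` and `outcome_date` for patients
#'   who ever meet the definition.
#' @export
ascertain_outcome <- function(data, spec, patient_ids = NULL) {
  dg <- data$diagnoses
  hit <- dg[dg$condition_code %in% spec$codes, ]
  if (!is.null(patient_ids)) hit <- hit[hit$patient_id %in% patient_ids, ]
  if (spec$definition == "code_and_two_rx") {
    rx <- data$prescriptions
    rx <- rx[rx$drug_class %in% spec$confirm_rx, ]
    ndates <- rx[, list(n = data.table::uniqueN(issue_date)), by = "patient_id"]
    confirmed <- ndates$patient_id[ndates$n >= 2L]
    hit <- hit[hit$patient_id %in% confirmed, ]
  }
  if (!nrow(hit)) {
    return(data.table::data.table(patient_id = integer(0),
                                  outcome_date = as.Date(integer(0),
                                                         origin = "1970-01-01")))
  }
  out <- hit[, list(outcome_date = min(event_date)), by = "patient_id"]
  if (spec$lead_time_years > 0) {
    out$outcome_date <- add_months(out$outcome_date,
                                   -12L * as.integer(spec$lead_time_years))
  }
  data.table::setorder(out, patient_id)
  out[]
}

utils::globalVariables(c("issue_date", "event_date", "patient_id"))
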