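#' Expand patient-trials into discrete 3-month person-time
#'
#' Each patient-trial contributes intervals `k = 0, 1, 2, ...` until the
#' earliest of: the outcome (an event in the interval containing it), death
#' (handled per the outcome's `death_handling`), administrative censoring
#' (registration end) or the maximum follow-up. Dates on an interval
#' boundary belong to the later interval (half-open convention). When two
#' terminal events fall in the same interval the precedence is
#' outcome > death > censoring. Exposure in an interval is at least one
#' study-drug prescription dated within it; cumulative exposure
#' (`cum_exposed_months`, the per-protocol dose clock) counts 3 months per
#' exposed interval *before* the current one, so it is predictable at
#' interval entry.
#'
#' @param trials patient-trial table from [assign_arms()] (needs `pt_id`,
#'   `patient_id`, `trial_id`, `index_date`, `arm`).
#' @param data an `ehr_dataset`.
#' @param spec an [outcome_spec()]; with `history_exclusion` set,
#'   patient-trials whose outcome is on or before the index date are
#'   dropped before expansion.
#' @param study_drug drug class defining exposure.
#' @param max_followup_months administrative maximum follow-up (default 144
#'   months, covering 10-year horizons with margin).
#' @param interval_days days per interval (91 by default; `t_months = 3k`).
#' @param carry extra columns of `trials` copied onto every interval row
#'   (those present are used; useful for `pair_id` or subgroup variables).
#' @return `data.table` with one row per person-interval: `pt_id`,
#'   `patient_id`, `trial_id`, `arm`, `k`, `t_months`, `exposed_now`,
#'   `cum_exposed_months`, `event`, `death`, `censored` (at most one of the
#'   last three is 1, in the terminal interval), plus any `carry` columns.
#' @export
expand_person_time <- function(trials, data, spec, study_drug,
                               max_followup_months = 144L,
                               interval_days = 91L,
                               carry = c("pair_id", "sex")) {
  tr <- data.table::as.data.table(trials)
  if (!nrow(tr)) stop("no patient-trials to expand")
  if (max_followup_months %% 3 != 0) stop("max_followup_months must be a multiple of 3")
  k_cap <- max_followup_months %/% 3L

  onset <- ascertain_outcome(data, spec, unique(tr$patient_id))
  tr <- merge(tr, onset, by = "patient_id", all.x = TRUE, sort = FALSE)
  if (spec$history_exclusion) tr <- tr[is.na(tr$outcome_date) |
                                         tr$outcome_date > tr$index_date, ]
  if (!nrow(tr)) stop("all patient-trials removed by the history exclusion")

  p <- data$patients
  i <- match(tr$patient_id, p$patient_id)
  d_out <- as.numeric(tr$outcome_date - tr$index_date)
  d_out[!is.na(d_out) & d_out < 0] <- NA  # pre-baseline outcomes never count as events
  d_death <- as.numeric(p$death_date[i] - tr$index_date)
  d_admin <- as.numeric(p$reg_end[i] - tr$index_date)

  k_out <- floor(d_out / interval_days)
  k_death <- floor(d_death / interval_days)
  k_cens <- pmin(floor(pmax(d_admin, 0) / interval_days), k_cap - 1L)

  if (spec$death_handling == "composite") {
    k_out <- pmin(k_out, k_death, na.rm = TRUE)
    k_out[is.na(d_out) & is.na(d_death)] <- NA
    k_death <- rep(NA_real_, nrow(tr))
  } else if (spec$death_handling == "censor") {
    k_cens <- pmin(k_cens, k_death, na.rm = TRUE)
    k_death <- rep(NA_real_, nrow(tr))
  }

  k_term <- pmin(k_out, k_death, k_cens, na.rm = TRUE)
  is_event <- !is.na(k_out) & k_out == k_term
  is_death <- !is.na(k_death) & k_death == k_term & !is_event
  K <- as.integer(k_term) + 1L

  idx <- rep(seq_len(nrow(tr)), K)
  keep <- intersect(carry, names(tr))
  pi <- data.table::data.table(
    pt_id = tr$pt_id[idx], patient_id = tr$patient_id[idx],
    trial_id = tr$trial_id[idx], arm = tr$arm[idx],
    k = sequence(K))
  pi$k <- pi$k - 1L
  pi$t_months <- 3L * pi$k
  for (cc in keep) pi[[cc]] <- tr[[cc]][idx]

  last <- pi$k == (K[idx] - 1L)
  pi$event <- as.integer(last & is_event[idx])
  pi$death <- as.integer(last & is_death[idx])
  pi$censored <- as.integer(last & !is_event[idx] & !is_death[idx])

  # exposure indicators from study-drug prescriptions
  rx <- data$prescriptions
  rx <- rx[rx$drug_class %in% study_drug, c("patient_id", "issue_date"), with = FALSE]
  jr <- merge(tr[, c("pt_id", "patient_id", "index_date"), with = FALSE], rx,
              by = "patient_id", allow.cartesian = TRUE)
  jr$k <- floor(as.numeric(jr$issue_date - jr$index_date) / interval_days)
  jr <- unique(jr[jr$k >= 0, c("pt_id", "k"), with = FALSE])
  jr$exposed_flag <- 1L
  pi <- merge(pi, jr, by = c("pt_id", "k"), all.x = TRUE, sort = FALSE)
  pi$exposed_now <- ifelse(is.na(pi$exposed_flag), 0L, 1L)
  pi$exposed_flag <- NULL
  data.table::setorder(pi, pt_id, k)
  pi[, cum_exposed_months := 3 * (cumsum(exposed_now) - exposed_now), by = "pt_id"]

  data.table::setcolorder(pi, c("pt_id", "patient_id", "trial_id", "arm", "k",
                                "t_months", "exposed_now", "cum_exposed_months",
                                "event", "death", "censored"))
  pi[]
}

utils::globalVariables(c("cum_exposed_months", "exposed_now", ":="))
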