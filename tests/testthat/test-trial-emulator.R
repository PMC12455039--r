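mini_ehr <- function(diag_days = integer(0), confirm_days = integer(0),
                     study_days = integer(0), death_day = NA_integer_,
                     reg_len = 8000L) {
  origin <- as.Date("2000-01-01")
  patients <- data.table::data.table(
    patient_id = 1L, sex = "F", birth_date = as.Date("1945-01-01"),
    reg_start = origin, reg_end = origin + reg_len,
    death_date = if (is.na(death_day)) as.Date(NA) else origin + death_day)
  structure(list(
    patients = patients,
    diagnoses = data.table::data.table(
      patient_id = rep(1L, length(diag_days)),
      event_date = origin + diag_days,
      condition_code = rep("cond_outcome", length(diag_days))),
    prescriptions = data.table::data.table(
      patient_id = rep(1L, length(confirm_days) + length(study_days)),
      issue_date = origin + c(confirm_days, study_days),
      drug_class = c(rep("rx_confirm", length(confirm_days)),
                     rep("rx_study", length(study_days)))),
    covariates = data.table::data.table(patient_id = integer(0),
                                        measurement_date = as.Date(integer(0)),
                                        name = character(0),
                                        value = character(0)),
    provenance = list()), class = "ehr_dataset")
}

one_trial <- function(ehr, index_day = 0L) {
  data.table::data.table(patient_id = 1L,
                         index_date = as.Date("2000-01-01") + index_day)
}

test_that("outcome ascertainment follows the code-plus-two-prescriptions rule", {
  ehr <- mini_ehr(diag_days = 500L, confirm_days = c(600L, 700L))
  got <- ascertain_outcome(ehr, default_outcome())
  expect_equal(got$outcome_date, as.Date("2000-01-01") + 500)

  only_one <- mini_ehr(diag_days = 500L, confirm_days = 600L)
  expect_equal(nrow(ascertain_outcome(only_one, default_outcome())), 0)

  # two prescriptions on the same date do not count as two
  same_day <- mini_ehr(diag_days = 500L, confirm_days = c(600L, 600L))
  expect_equal(nrow(ascertain_outcome(same_day, default_outcome())), 0)

  # plain code definition needs no confirmation
  got2 <- ascertain_outcome(only_one,
                            outcome_spec("alt", "plain_code", codes = "cond_outcome"))
  expect_equal(got2$outcome_date, as.Date("2000-01-01") + 500)
})

test_that("lead time backdates the ascertained onset by whole years", {
  origin <- as.Date("2000-01-01")
  ehr <- mini_ehr(diag_days = as.integer(as.Date("2015-06-01") - origin),
                  confirm_days = c(6000L, 6100L))
  spec <- default_outcome(lead_time_years = 3)
  got <- ascertain_outcome(ehr, spec)
  expect_equal(got$outcome_date, as.Date("2012-06-01"))
})

test_that("unknown outcome definitions are rejected", {
  expect_error(outcome_spec("x", "nonsense", codes = "c"), "unknown")
  expect_error(outcome_spec("x", "code_and_two_rx", codes = "c"), "confirm_rx")
})

test_that("arm assignment uses the first-3-months rule", {
  for (case in list(list(days = 10L, arm = "initiator"),
                    list(days = 100L, arm = "non-initiator"),
                    list(days = integer(0), arm = "non-initiator"))) {
    ehr <- mini_ehr(study_days = case$days)
    tr <- assign_arms(one_trial(ehr), ehr, "rx_study")
    expect_equal(tr$arm, case$arm)
  }
  # a prescription on the index date itself counts as initiation
  ehr <- mini_ehr(study_days = 0L)
  expect_equal(assign_arms(one_trial(ehr), ehr, "rx_study")$arm, "initiator")
})

test_that("baseline covariates respect their lookback windows", {
  ehr <- mini_ehr()
  origin <- as.Date("2000-01-01")
  ehr$covariates <- data.table::data.table(
    patient_id = 1L,
    measurement_date = origin + c(-400L, -100L, -100L),
    name = c("hosp_count", "hosp_count", "recent_med"),
    value = c("3", "1", "1"))
  tr <- assign_arms(one_trial(ehr, 0L), ehr, "rx_study",
                    covariate_lookback = list(hosp_count = 365, recent_med = 180))
  expect_equal(tr$hosp_count, 1)     # the -400d measurement is outside 365d
  expect_equal(tr$recent_med, 1)
  tr2 <- assign_arms(one_trial(ehr, 0L), ehr, "rx_study",
                     covariate_lookback = list(recent_med = 30))
  expect_equal(tr2$hosp_count, 1)    # unlimited lookback takes the latest
  expect_null(tr2$recent_med)        # no measurement inside its 30d window
})

test_that("person-time expansion places terminal events in the right interval", {
  # outcome 8 months (243 days) after index: k = floor(243/91) = 2
  ehr <- mini_ehr(diag_days = 243L, confirm_days = c(300L, 400L))
  pt <- expand_person_time(assign_arms(one_trial(ehr), ehr, "rx_study"),
                           ehr, default_outcome(), "rx_study")
  expect_equal(pt$k, 0:2)
  expect_equal(pt$event, c(0L, 0L, 1L))
  expect_equal(sum(pt$death) + sum(pt$censored), 0)

  # death at 4 months (122 days) with death as censoring: k=0 clean, k=1 censored
  ehr2 <- mini_ehr(death_day = 122L)
  pt2 <- expand_person_time(assign_arms(one_trial(ehr2), ehr2, "rx_study"),
                            ehr2, default_outcome(death_handling = "censor"),
                            "rx_study")
  expect_equal(pt2$k, 0:1)
  expect_equal(pt2$censored, c(0L, 1L))
  expect_equal(sum(pt2$event) + sum(pt2$death), 0)

  # same death as a competing event
  pt3 <- expand_person_time(assign_arms(one_trial(ehr2), ehr2, "rx_study"),
                            ehr2,
                            default_outcome(death_handling = "competing_event"),
                            "rx_study")
  expect_equal(pt3$death, c(0L, 1L))

  # composite: death counts as the event
  pt4 <- expand_person_time(assign_arms(one_trial(ehr2), ehr2, "rx_study"),
                            ehr2, default_outcome(death_handling = "composite"),
                            "rx_study")
  expect_equal(pt4$event, c(0L, 1L))
})

test_that("continuous prescribing makes the dose clock track time since baseline", {
  ehr <- mini_ehr(study_days = seq(0L, 2000L, by = 91L))
  pt <- expand_person_time(assign_arms(one_trial(ehr), ehr, "rx_study"),
                           ehr, default_outcome(), "rx_study",
                           max_followup_months = 60L)
  expect_true(all(pt$exposed_now == 1))
  expect_equal(pt$cum_exposed_months, pt$t_months)
})

test_that("history exclusion drops patient-trials with pre-baseline outcomes", {
  ehr <- mini_ehr(diag_days = -50L, confirm_days = c(10L, 20L), reg_len = 4000L)
  ehr$patients$reg_start <- as.Date("1995-01-01")
  spec <- default_outcome(history_exclusion = TRUE)
  expect_error(expand_person_time(assign_arms(one_trial(ehr), ehr, "rx_study"),
                                  ehr, spec, "rx_study"),
               "history exclusion")
  # without the exclusion the pre-baseline outcome never counts as an event
  pt <- expand_person_time(assign_arms(one_trial(ehr), ehr, "rx_study"),
                           ehr, default_outcome(), "rx_study",
                           max_followup_months = 12L)
  expect_equal(sum(pt$event), 0)
})

test_that("interval bookkeeping invariants hold on generated data", {
  ehr <- generate_population(sim_config(400, seed = 17,
                                        death_hazard = list(base = 0.008)))
  el <- data.table::data.table(patient_id = ehr$patients$patient_id,
                               index_date = ehr$patients$reg_start + 370L)
  el <- el[el$index_date < ehr$patients$reg_end &
             (is.na(ehr$patients$death_date) |
                el$index_date < ehr$patients$death_date), ]
  tr <- assign_arms(el, ehr, "rx_study")
  pt <- expand_person_time(tr, ehr, default_outcome(death_handling = "competing_event"),
                           "rx_study")
  # at most one terminal flag, only in the last interval, no gaps in k
  per <- pt[, list(n = .N, kmax = max(k),
                   terminals = sum(event + death + censored),
                   last_flag = sum((event + death + censored) * (k == max(k)))),
            by = "pt_id"]
  expect_true(all(per$n == per$kmax + 1))       # no gaps
  expect_true(all(per$terminals == 1))          # exactly one terminal mark
  expect_true(all(per$last_flag == 1))          # ... in the final interval
  expect_true(all(pt$cum_exposed_months <= pt$t_months))
  expect_true(all(pt[, diff(cum_exposed_months) >= 0, by = "pt_id"]$V1))
})

test_that("composite events equal outcome-first plus death-first competing counts", {
  ehr <- generate_population(sim_config(600, seed = 23,
                                        death_hazard = list(base = 0.01)))
  el <- data.table::data.table(patient_id = ehr$patients$patient_id,
                               index_date = ehr$patients$reg_start + 370L)
  el <- el[el$index_date < ehr$patients$reg_end &
             (is.na(ehr$patients$death_date) |
                el$index_date < ehr$patients$death_date), ]
  tr <- assign_arms(el, ehr, "rx_study")
  comp <- expand_person_time(tr, ehr, default_outcome(death_handling = "composite"),
                             "rx_study")
  cmpt <- expand_person_time(tr, ehr,
                             default_outcome(death_handling = "competing_event"),
                             "rx_study")
  expect_equal(sum(comp$event), sum(cmpt$event) + sum(cmpt$death))
  expect_equal(nrow(comp), nrow(cmpt))  # identical risk sets
})

test_that("total person-intervals match a day-level scan collapsed to 3-month bins", {
  ehr <- generate_population(sim_config(80, seed = 3,
                                        death_hazard = list(base = 0.01)))
  el <- data.table::data.table(patient_id = ehr$patients$patient_id,
                               index_date = ehr$patients$reg_start)
  tr <- assign_arms(el, ehr, "rx_study")
  spec <- default_outcome(death_handling = "censor")
  pt <- expand_person_time(tr, ehr, spec, "rx_study", max_followup_months = 144L)
  onset <- ascertain_outcome(ehr, spec)
  for (r in seq_len(nrow(tr))) {
    p <- as.data.frame(ehr$patients)
    p <- p[p$patient_id == tr$patient_id[r], ]
    idx <- tr$index_date[r]
    d_out <- onset$outcome_date[match(tr$patient_id[r], onset$patient_id)]
    ends <- c(out = if (!is.na(d_out) && d_out >= idx)
                floor(as.numeric(d_out - idx) / 91) else Inf,
              death = if (!is.na(p$death_date))
                floor(as.numeric(p$death_date - idx) / 91) else Inf,
              admin = min(floor(as.numeric(p$reg_end - idx) / 91), 47))
    expect_equal(sum(pt$pt_id == tr$pt_id[r]), min(ends) + 1)
  }
})
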