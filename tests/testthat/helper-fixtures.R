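# Fixtures are built in code; oracles here are deliberately naive
# implementations kept independent of the package internals.

as_date <- function(x) as.Date(x)

# Hand-built record dataset: three patients, abstract codes.
#  p1: index condition, study rx at reg+200d then nothing (re-initiator
#      candidate for later trials), outcome never.
#  p2: index condition, never treated, outcome diagnosis + 2 confirm rx.
#  p3: no index condition.
tiny_ehr <- function() {
  patients <- data.table::data.table(
    patient_id = 1:3,
    sex = c("F", "M", "F"),
    birth_date = as_date(c("1950-06-15", "1948-03-01", "1952-11-30")),
    reg_start = as_date(c("1995-01-01", "1996-01-01", "1997-01-01")),
    reg_end = as_date(c("2020-01-01", "2018-06-01", "2019-01-01")),
    death_date = as_date(c(NA, NA, NA)))
  diagnoses <- data.table::data.table(
    patient_id = c(1L, 2L, 2L),
    event_date = as_date(c("1995-01-01", "1996-01-01", "2010-05-20")),
    condition_code = c("cond_index", "cond_index", "cond_outcome"))
  prescriptions <- data.table::data.table(
    patient_id = c(1L, 2L, 2L),
    issue_date = as_date(c("2005-03-01", "2010-06-15", "2010-07-20")),
    drug_class = c("rx_study", "rx_confirm", "rx_confirm"))
  covariates <- data.table::data.table(
    patient_id = rep(1:3, each = 2),
    measurement_date = rep(as_date(c("1995-01-01", "1996-01-01", "1997-01-01")),
                           each = 2),
    name = rep(c("severity", "biomarker"), 3),
    value = as.character(c(1, 0.5, 0, -0.2, 1, 1.1)))
  structure(list(patients = patients, diagnoses = diagnoses,
                 prescriptions = prescriptions, covariates = covariates,
                 provenance = list(seed = NA)),
            class = "ehr_dataset")
}

default_elig <- function(...) {
  eligibility_spec(index_condition = "cond_index",
                   exclusion_conditions = "cond_outcome",
                   exclusion_drug_classes = "rx_confirm",
                   washout_drug_class = "rx_study", ...)
}

default_outcome <- function(...) {
  outcome_spec("primary", "code_and_two_rx", codes = "cond_outcome",
               confirm_rx = "rx_confirm", ...)
}

# Build eligible patient-trials across a whole grid.
eligible_all <- function(ehr, spec, grid) {
  l <- lapply(seq_along(grid$points), function(i) {
    e <- assess_eligibility(ehr, spec, grid, i)
    if (nrow(e)) e$trial_id <- i
    e
  })
  data.table::rbindlist(l[vapply(l, nrow, 0L) > 0])
}

run_stages <- function(ehr, grid, elig = default_elig(),
                       covs = c("severity", "biomarker", "comorbidity", "sex"),
                       caliper = 0.05) {
  el <- eligible_all(ehr, elig, grid)
  tr <- assign_arms(el, ehr, "rx_study")
  ps <- fit_propensity(tr, covs)
  mc <- greedy_match(ps, tr, caliper)
  list(trials = tr, ps = ps, cohort = mc)
}

# Trial-level synthetic units with confounded initiation (no follow-up),
# for propensity/matching/balance tests.
sim_trial_units <- function(n, seed, beta0 = -1.2,
                            beta = c(x1 = 0.7, x2 = 0.5, x3 = 0.4)) {
  set.seed(seed)
  x1 <- stats::rbinom(n, 1, 0.4)
  x2 <- stats::rnorm(n)
  x3 <- stats::rbinom(n, 1, 0.3)
  lp <- beta0 + beta[["x1"]] * x1 + beta[["x2"]] * x2 + beta[["x3"]] * x3
  data.table::data.table(
    pt_id = seq_len(n), patient_id = seq_len(n), trial_id = 1L,
    index_date = as_date("2000-01-01"),
    arm = ifelse(stats::runif(n) < stats::plogis(lp), "initiator", "non-initiator"),
    x1 = x1, x2 = x2, x3 = x3)
}

# Person-interval simulator for hazard-model tests: n units per arm, K
# intervals, constant baseline discrete hazard h0, odds multiplied by
# or_arm for initiators; censoring only at K.
sim_intervals <- function(n_per_arm, K, h0, or_arm = 1, seed = 1,
                          subgroup_or = NULL) {
  set.seed(seed)
  units <- data.table::data.table(
    pt_id = seq_len(2 * n_per_arm),
    arm = rep(c("initiator", "non-initiator"), each = n_per_arm))
  units$g <- rep(c("a", "b"), length.out = nrow(units))
  rows <- list()
  for (u in seq_len(nrow(units))) {
    A <- as.integer(units$arm[u] == "initiator")
    or_g <- if (!is.null(subgroup_or) && units$g[u] == "b") subgroup_or else 1
    h <- stats::plogis(stats::qlogis(h0) + A * log(or_arm * or_g))
    ev <- stats::rbinom(K, 1, h)
    kend <- if (any(ev == 1)) which(ev == 1)[1] else K
    k <- seq_len(kend) - 1L
    rows[[u]] <- data.table::data.table(
      pt_id = units$pt_id[u], patient_id = units$pt_id[u], trial_id = 1L,
      arm = units$arm[u], g = units$g[u], k = k, t_months = 3L * k,
      exposed_now = A, cum_exposed_months = 3 * A * k,
      event = c(rep(0L, kend - 1L), as.integer(any(ev == 1))),
      death = 0L,
      censored = c(rep(0L, kend - 1L), as.integer(!any(ev == 1))))
  }
  data.table::rbindlist(rows)
}

# Discrete-time product-limit (Kaplan-Meier on the interval grid): hazard in
# interval k = events / at-risk among rows with that t.
product_limit <- function(intervals) {
  dt <- data.table::as.data.table(intervals)
  tab <- dt[, list(events = sum(event), at_risk = .N), by = "t_months"]
  data.table::setorder(tab, t_months)
  data.table::data.table(t_months = c(0L, tab$t_months + 3L),
                         risk = c(0, 1 - cumprod(1 - tab$events / tab$at_risk)))
}

# Brute-force greedy matching: initiators in descending score order, each
# takes the nearest remaining control by linear scan (ties to the
# lower-score control), skipped beyond the caliper.
greedy_oracle <- function(s_init, s_ctrl, caliper) {
  avail <- rep(TRUE, length(s_ctrl))
  out_i <- integer(0); out_j <- integer(0)
  for (ii in order(-s_init, seq_along(s_init))) {
    d <- abs(s_ctrl - s_init[ii])
    d[!avail] <- Inf
    if (!any(is.finite(d))) next
    best <- min(d)
    if (best > caliper) next
    cand <- which(d == best)
    j <- cand[which.min(s_ctrl[cand])]
    avail[j] <- FALSE
    out_i <- c(out_i, ii); out_j <- c(out_j, j)
  }
  data.table::data.table(i = out_i, j = out_j)
}

# Day-level brute-force eligibility scan for one patient at one index date.
eligible_bruteforce <- function(ehr, spec, pid, index_date) {
  p <- as.data.frame(ehr$patients)
  p <- p[p$patient_id == pid, ]
  if (!nrow(p)) return(FALSE)
  dg <- as.data.frame(ehr$diagnoses)
  dg <- dg[dg$patient_id == pid, ]
  rx <- as.data.frame(ehr$prescriptions)
  rx <- rx[rx$patient_id == pid, ]
  age <- as.numeric(index_date - p$birth_date) / 365.25
  ok <- index_date >= p$reg_start && index_date < p$reg_end &&
    (is.na(p$death_date) || index_date < p$death_date) &&
    age >= spec$age_min && age < spec$age_max + 1 &&
    as.numeric(index_date - p$reg_start) >= spec$min_history_days &&
    any(dg$condition_code %in% spec$index_condition &
          dg$event_date <= index_date) &&
    !any(dg$condition_code %in% spec$exclusion_conditions &
           dg$event_date <= index_date) &&
    !any(rx$drug_class %in% spec$exclusion_drug_classes &
           rx$issue_date <= index_date)
  washout <- if (spec$allow_reinitiators) {
    any(rx$drug_class %in% spec$washout_drug_class &
          rx$issue_date < index_date &
          rx$issue_date > index_date - spec$washout_days)
  } else {
    any(rx$drug_class %in% spec$washout_drug_class & rx$issue_date < index_date)
  }
  ok && !washout
}
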