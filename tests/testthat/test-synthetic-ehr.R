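test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(10, true_effect = -1), "true_effect")
  expect_error(sim_config(10, discontinuation_prob = 1.5), "discontinuation_prob")
  expect_error(sim_config(10, outcome_hazard = list(base = 1.2)), "outcome_hazard")
  expect_error(
    sim_config(10, initiation_model = list(intercept = 0, coef = c(nope = 1))),
    "nope")
})

test_that("impossible initiation yields a dataset with no study prescriptions", {
  cfg <- sim_config(300, seed = 2,
                    initiation_model = list(intercept = -Inf, coef = NULL))
  ehr <- generate_population(cfg)
  expect_equal(sum(ehr$prescriptions$drug_class == "rx_study"), 0)
})

test_that("zero death hazard leaves every death date missing", {
  cfg <- sim_config(300, seed = 2, death_hazard = list(base = 0))
  ehr <- generate_population(cfg)
  expect_true(all(is.na(ehr$patients$death_date)))
})

test_that("identical configurations reproduce byte-identical tables", {
  cfg <- sim_config(400, seed = 99)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  for (tab in c("patients", "diagnoses", "prescriptions", "covariates"))
    expect_identical(a[[tab]], b[[tab]])
  c2 <- generate_population(sim_config(400, seed = 100))
  expect_false(identical(a$prescriptions, c2$prescriptions))
})

test_that("never-exposed interval event rate matches the configured hazard", {
  # covariate-free outcome so the configured baseline is the truth
  h0 <- 0.006
  cfg <- sim_config(2000, seed = 1, true_effect = 1.0,
                    outcome_hazard = list(base = h0, coef = NULL),
                    initiation_model = list(intercept = -Inf, coef = NULL))
  ehr <- generate_population(cfg)
  # reconstruct interval-level event indicators among all never-exposed time
  os <- default_outcome()
  el <- data.table::data.table(patient_id = ehr$patients$patient_id,
                               index_date = ehr$patients$reg_start)
  tr <- assign_arms(el, ehr, "rx_study")
  pt <- expand_person_time(tr, ehr, os, "rx_study", max_followup_months = 144L)
  rate <- sum(pt$event) / nrow(pt)  # each row is one at-risk interval
  se <- sqrt(h0 * (1 - h0) / nrow(pt))
  expect_lt(abs(rate - h0), 3 * se)
})

test_that("null effect with no confounding gives equal exposed and unexposed rates", {
  cfg <- sim_config(3000, seed = 7, true_effect = 1.0,
                    initiation_model = list(intercept = -2.5, coef = NULL),
                    outcome_hazard = list(base = 0.01, coef = NULL),
                    discontinuation_prob = 0.05)
  ehr <- generate_population(cfg)
  os <- default_outcome()
  el <- data.table::data.table(patient_id = ehr$patients$patient_id,
                               index_date = ehr$patients$reg_start)
  tr <- assign_arms(el, ehr, "rx_study")
  pt <- expand_person_time(tr, ehr, os, "rx_study")
  r1 <- mean(pt$event[pt$exposed_now == 1])
  r0 <- mean(pt$event[pt$exposed_now == 0])
  se <- sqrt(r0 * (1 - r0) * (1 / sum(pt$exposed_now == 1) +
                                1 / sum(pt$exposed_now == 0)))
  expect_lt(abs(r1 - r0), 3.5 * se)
})

test_that("a confounder of initiation and outcome biases the crude rate ratio upward", {
  base <- list(n = 4000, h = 0.008)
  mk <- function(init_coef) {
    cfg <- sim_config(base$n, seed = 5, true_effect = 1.0,
                      initiation_model = list(intercept = -3,
                                              coef = c(severity = init_coef)),
                      outcome_hazard = list(base = base$h, coef = c(severity = 1.2)),
                      discontinuation_prob = 0.05)
    ehr <- generate_population(cfg)
    el <- data.table::data.table(patient_id = ehr$patients$patient_id,
                                 index_date = ehr$patients$reg_start)
    tr <- assign_arms(el, ehr, "rx_study")
    pt <- expand_person_time(tr, ehr, default_outcome(), "rx_study")
    mean(pt$event[pt$exposed_now == 1]) / mean(pt$event[pt$exposed_now == 0])
  }
  crude_confounded <- mk(2.0)
  crude_null <- mk(0.0)
  expect_gt(crude_confounded, crude_null)
  expect_gt(crude_confounded, 1.15)  # clearly away from the true null
})

test_that("marginal-risk oracle matches closed forms", {
  cfg <- sim_config(10, outcome_hazard = list(base = 0.01, coef = NULL))
  r <- true_marginal_risk(cfg, "never-treated", 120)
  expect_equal(as.numeric(r), 1 - 0.99^40, tolerance = 1e-12)
  expect_equal(attr(r, "method"), "closed_form")

  # null symmetry
  ra <- true_marginal_risk(cfg, "always-treated", 120)
  expect_equal(as.numeric(ra), as.numeric(r), tolerance = 1e-12)

  # single interval odds algebra: odds 0.01/0.99 doubled
  cfg2 <- sim_config(10, true_effect = 2.0,
                     outcome_hazard = list(base = 0.01, coef = NULL))
  r1 <- true_marginal_risk(cfg2, "always-treated", 3)
  odds <- 2 * 0.01 / 0.99
  expect_equal(as.numeric(r1), odds / (1 + odds), tolerance = 1e-12)

  # enumeration over a binary covariate agrees with manual weighting
  cfg3 <- sim_config(10, true_effect = 1.5,
                     covariate_spec = list(list(name = "severity",
                                                type = "binary", prob = 0.3)),
                     initiation_model = list(intercept = -2, coef = NULL),
                     outcome_hazard = list(base = 0.01, coef = c(severity = 0.7)),
                     death_hazard = list(base = 0.003))
  r3 <- true_marginal_risk(cfg3, "never-treated", 6)
  h_lo <- plogis(qlogis(0.01)); h_hi <- plogis(qlogis(0.01) + 0.7)
  manual <- 0.7 * (1 - (1 - h_lo)^2) + 0.3 * (1 - (1 - h_hi)^2)
  expect_equal(as.numeric(r3), manual, tolerance = 1e-12)
  expect_equal(attr(r3, "method"), "enumeration")

  expect_error(true_marginal_risk(cfg, "never-treated", 100), "multiple")
})

test_that("round-trip through delimited text preserves the dataset", {
  cfg <- sim_config(100, seed = 21)
  ehr <- generate_population(cfg)
  dir <- withr::local_tempdir()
  write_ehr_dataset(ehr, dir)
  expect_true(all(file.exists(file.path(dir, c("patients.csv", "metadata.json")))))
  back <- read_ehr_dataset(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(ehr$patients))
  expect_equal(as.data.frame(back$prescriptions), as.data.frame(ehr$prescriptions))
  expect_equal(back$provenance$seed, 21)
})

test_that("structural invariants hold on generated data", {
  ehr <- generate_population(sim_config(500, seed = 13,
                                        death_hazard = list(base = 0.01)))
  expect_silent(validate_ehr(ehr))
  p <- ehr$patients
  expect_true(all(p$reg_start < p$reg_end))
  died <- !is.na(p$death_date)
  expect_true(all(p$reg_end[died] <= p$death_date[died]))
})
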