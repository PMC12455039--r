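#' Configuration for a full sequential-emulation run
#'
#' Bundles every stage's settings: the data source (a dataset, a directory
#' of tables, or a [sim_config()] to simulate from), the trial grid, the
#' eligibility rules, the outcome definitions, the propensity-score
#' covariates, the matching caliper, the bootstrap settings, the reporting
#' horizons and the sensitivity toggles. All randomness flows from the
#' single `seed` (the generator uses it directly; the bootstrap uses
#' `seed + 1`).
#'
#' @param data an `ehr_dataset`, a directory path for
#'   [read_ehr_dataset()], or a [sim_config()].
#' @param grid a [trial_grid()].
#' @param eligibility an [eligibility_spec()].
#' @param outcomes list of [outcome_spec()]s (a single spec is accepted).
#' @param ps_covariates covariate names for the propensity model (age is
#'   never included; the grid matches on it exactly).
#' @param study_drug drug class under study (arm assignment and exposure).
#' @param caliper matching caliper on the probability scale.
#' @param bootstrap a [bootstrap_config()].
#' @param horizons reporting horizons in months (default 60 and 120).
#' @param estimands estimands to compute (`"itt"`, `"pp"` or both).
#' @param max_followup_months administrative end of follow-up.
#' @param covariate_lookback named lookback windows passed to
#'   [assign_arms()].
#' @param subgroups optional baseline columns for interaction tests.
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(data, grid, eligibility, outcomes, ps_covariates,
                       study_drug, caliper = 0.05,
                       bootstrap = bootstrap_config(),
                       horizons = c(60L, 120L),
                       estimands = c("itt", "pp"),
                       max_followup_months = 144L,
                       covariate_lookback = list(),
                       subgroups = character(0),
                       seed = 1L) {
  if (inherits(outcomes, "outcome_spec")) outcomes <- list(outcomes)
  stopifnot(inherits(grid, "trial_grid"), inherits(eligibility, "eligibility_spec"),
            all(vapply(outcomes, inherits, TRUE, "outcome_spec")))
  structure(list(data = data, grid = grid, eligibility = eligibility,
                 outcomes = outcomes, ps_covariates = ps_covariates,
                 study_drug = study_drug, caliper = caliper,
                 bootstrap = bootstrap, horizons = as.integer(horizons),
                 estimands = match.arg(estimands, several.ok = TRUE),
                 max_followup_months = as.integer(max_followup_months),
                 covariate_lookback = covariate_lookback,
                 subgroups = subgroups, seed = as.integer(seed)),
            class = "run_config")
}

resolve_data <- function(config) {
  d <- config$data
  if (inherits(d, "ehr_dataset")) return(d)
  if (inherits(d, "sim_config")) {
    d$seed <- config$seed
    return(generate_population(d))
  }
  if (is.character(d)) return(read_ehr_dataset(d))
  stop("data must be an ehr_dataset, a sim_config, or a directory path")
}

validate_run_config <- function(config, data) {
  known <- c(unique(data$covariates$name), "sex")
  bad <- setdiff(config$ps_covariates, known)
  if (length(bad))
    stop("unknown covariate name(s) in ps_covariates: ",
         paste(bad, collapse = ", "))
  if (any(config$horizons %% 3 != 0))
    stop("horizons must lie on the 3-month grid")
  if (any(config$horizons > config$max_followup_months))
    stop("horizons exceed max_followup_months")
  invisible(config)
}

#' Run the full sequential trial emulation
#'
#' Executes every stage in order: load or simulate the records, screen
#' eligibility at each trial point, assign arms and baseline covariates,
#' fit the propensity model, match 1:1 within trial, then for each outcome
#' expand the matched person-time and estimate intention-to-treat and
#' per-protocol effects with bootstrap confidence intervals. Per-trial
#' eligible/initiator/matched counts are accumulated for flow reporting.
#' Two runs with an identical configuration produce identical results.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every result table is
#'   written as comma-separated text together with a machine-readable
#'   `manifest.json` recording seeds and versions.
#' @return list of class `run_result` with `eligibility`, `trial_counts`,
#'   `trials` (arm-assigned patient-trials), `propensity`, `cohort`,
#'   `balance`, `effects` (table), `curves`, `boot` (per outcome/estimand),
#'   `subgroup_tests` and `manifest`.
#' @export
run_emulation <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  data <- resolve_data(config)
  validate_run_config(config, data)
  grid <- config$grid

  elig_list <- vector("list", length(grid))
  for (i in seq_along(grid$points)) {
    e <- assess_eligibility(data, config$eligibility, grid, i)
    if (nrow(e)) e$trial_id <- i
    elig_list[[i]] <- e
  }
  eligibility <- data.table::rbindlist(elig_list[vapply(elig_list, nrow, 0L) > 0])
  if (!nrow(eligibility)) stop("no eligible patient-trials under this configuration")

  trials <- assign_arms(eligibility, data, config$study_drug,
                        covariate_lookback = config$covariate_lookback)
  ps <- fit_propensity(trials, config$ps_covariates)
  cohort <- greedy_match(ps, trials, caliper = config$caliper)
  if (!nrow(cohort$pairs)) stop("matching produced no pairs")
  balance <- balance_table(trials, cohort, config$ps_covariates)

  counts <- trials[, list(eligible = .N,
                          initiators = sum(arm == "initiator")),
                   by = "trial_id"]
  mcounts <- cohort$pairs[, list(matched_pairs = .N), by = "trial_id"]
  trial_counts <- merge(counts, mcounts, by = "trial_id", all.x = TRUE)
  trial_counts$matched_pairs[is.na(trial_counts$matched_pairs)] <- 0L

  boot_cfg <- config$bootstrap
  boot_cfg$seed <- config$seed + 1L
  effects_rows <- list()
  curves <- list(); boot <- list(); subgroup_tests <- list()
  for (os in config$outcomes) {
    pt <- expand_person_time(cohort$trials, data, os, config$study_drug,
                             max_followup_months = config$max_followup_months,
                             carry = c("pair_id", "sex", config$subgroups))
    for (est in config$estimands) {
      bs <- bootstrap_ci(pt, cohort, estimand = est,
                         horizons = config$horizons, config = boot_cfg)
      boot[[paste(os$name, est, sep = ".")]] <- bs
      full_fit <- if (est == "itt") fit_itt(pt) else fit_pp(pt)
      regs <- if (est == "itt") c("initiator", "non-initiator")
              else c("always-treated", "never-treated")
      cv <- data.table::rbindlist(lapply(regs, function(r)
        cumulative_incidence(full_fit, r, max(config$horizons),
                             observed_max_t = max(pt$t_months))))
      cv$outcome <- os$name; cv$estimand <- toupper(est)
      curves[[paste(os$name, est, sep = ".")]] <- cv
      for (h in names(bs$estimates)) {
        e <- bs$estimates[[h]]
        effects_rows[[length(effects_rows) + 1L]] <- data.table::data.table(
          outcome = os$name, estimand = toupper(est),
          horizon_months = e$horizon_months,
          events_treated = sum(pt$event[pt$arm == "initiator"]),
          events_comparator = sum(pt$event[pt$arm != "initiator"]),
          units_per_arm = nrow(cohort$pairs),
          risk1_pct = e$risk1, risk0_pct = e$risk0,
          rr = e$rr, rr_lo = e$ci$rr[1], rr_hi = e$ci$rr[2],
          rd_pp = e$rd, rd_lo = e$ci$rd[1], rd_hi = e$ci$rd[2],
          nnt = e$nnt, nnt_label = e$nnt_label,
          nnt_lo = e$ci$nnt[1], nnt_hi = e$ci$nnt[2])
      }
    }
    for (sg in config$subgroups) {
      key <- paste(os$name, sg, sep = ".")
      subgroup_tests[[key]] <- subgroup_interaction(
        pt, sg, horizon_months = max(config$horizons))
    }
  }
  effects <- data.table::rbindlist(effects_rows)
  manifest <- list(package = "seqtte",
                   version = as.character(utils::packageVersion("seqtte")),
                   seed = config$seed,
                   bootstrap_seed = boot_cfg$seed,
                   n_trials = length(grid),
                   grid_axis = grid$axis,
                   n_eligible_patient_trials = nrow(trials),
                   n_initiators = sum(trials$arm == "initiator"),
                   n_matched_pairs = nrow(cohort$pairs),
                   outcomes = vapply(config$outcomes, `[[`, "", "name"),
                   horizons = config$horizons,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- structure(list(eligibility = eligibility,
                           trial_counts = trial_counts,
                           trials = trials, propensity = ps, cohort = cohort,
                           balance = balance, effects = effects,
                           curves = curves, boot = boot,
                           subgroup_tests = subgroup_tests,
                           manifest = manifest),
                      class = "run_result")
  if (!is.null(out_dir)) write_run_result(result, out_dir)
  result
}

#' @export
print.run_result <- function(x, ...) {
  m <- x$manifest
  cat("<run_result>", m$n_trials, "trials;", m$n_eligible_patient_trials,
      "eligible patient-trials;", m$n_matched_pairs, "matched pairs\n")
  print(x$effects)
  invisible(x)
}

write_run_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name) data.table::fwrite(obj, file.path(out_dir, name),
                                              dateTimeAs = "ISO")
  w(result$eligibility, "eligibility.csv")
  w(result$trial_counts, "trial_counts.csv")
  w(result$cohort$pairs, "matched_pairs.csv")
  w(result$balance, "balance.csv")
  w(result$effects, "effects.csv")
  w(data.table::rbindlist(result$curves), "curves.csv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

utils::globalVariables(c("arm", "trial_id"))
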