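#' Fit the propensity-score model
#'
#' Logistic regression of treatment initiation on baseline covariates.
#' Following the matched sequential-trial design, age is not entered (the
#' trial grid matches on it exactly) and every continuous covariate is
#' entered with both its linear and quadratic term; categorical covariates
#' (including explicit "Unknown" levels) enter as factors.
#'
#' @param trials patient-trial table from [assign_arms()].
#' @param covariates character vector of covariate column names to use.
#' @return an object of class `propensity_fit`: named `coefficients`,
#'   per-patient-trial `scores` in (0,1), the `glm` `model`, and
#'   diagnostics (`converged`, `iterations`, `log_likelihood`).
#' @export
fit_propensity <- function(trials, covariates) {
  tr <- data.table::as.data.table(trials)
  missing_cov <- setdiff(covariates, names(tr))
  if (length(missing_cov))
    stop("covariates absent from the patient-trial table: ",
         paste(missing_cov, collapse = ", "))
  if (length(unique(tr$arm)) < 2L)
    stop("need at least one unit in each arm to fit a propensity model")
  for (cv in covariates) {
    if (anyNA(tr[[cv]]))
      stop("covariate `", cv, "` has missing values; encode unknowns as an ",
           "explicit category")
  }
  if (any(covariates != make.names(covariates)))
    stop("covariate names must be syntactically valid R names")
  terms <- vapply(covariates, function(cv) {
    x <- tr[[cv]]
    if (is.numeric(x) && length(unique(x)) > 2L)
      sprintf("%s + I(%s^2)", cv, cv)
    else cv
  }, "")
  f <- stats::as.formula(paste(".init ~", paste(terms, collapse = " + ")))
  df <- as.data.frame(tr[, covariates, with = FALSE])
  df$.init <- as.integer(tr$arm == "initiator")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = df, family = stats::binomial(), model = FALSE,
               y = FALSE),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  if (sep_warn || any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
    cf <- stats::coef(fit)
    worst <- names(which.max(abs(cf[names(cf) != "(Intercept)"])))
    stop("perfect or quasi-perfect separation in the propensity model ",
         "(largest coefficient: ", worst, ")", call. = FALSE)
  }
  if (!fit$converged) {
    stop(sprintf("propensity model did not converge after %d iterations (deviance %.3f)",
                 fit$iter, fit$deviance))
  }
  sc <- as.numeric(stats::predict(fit, type = "response"))
  structure(list(coefficients = stats::coef(fit),
                 scores = sc,
                 model = fit,
                 converged = fit$converged,
                 iterations = fit$iter,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 covariates = covariates),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit>", length(x$scores), "patient-trials,",
      length(x$coefficients), "terms; score range",
      sprintf("%.3f-%.3f", min(x$scores), max(x$scores)), "\n")
  invisible(x)
}

#' Greedy nearest-neighbour 1:1 matching within a caliper
#'
#' Matches each initiator to the unmatched non-initiator with the closest
#' propensity score, processing initiators in descending score order (ties
#' broken by unit id) and skipping initiators whose nearest available
#' control lies further than the caliper. Matching is 1:1 without
#' replacement and is performed within trial, which enforces exact matching
#' on the trial's index age by construction of the sequential design.
#'
#' @param fit a [fit_propensity()] result (scores aligned with `trials`
#'   rows), or a numeric score vector.
#' @param trials the patient-trial table the scores refer to.
#' @param caliper maximum |score difference| for an acceptable pair, on the
#'   probability scale (default 0.05); must be > 0. `Inf` disables it.
#' @param within_trial match only within the same `trial_id` (default TRUE).
#' @return an object of class `matched_cohort`: `pairs` (one row per
#'   matched pair with unit ids, scores and distance), the `caliper`, and
#'   the matched patient-trial table `trials` (initiators and their
#'   controls, with a `pair_id` column).
#' @export
greedy_match <- function(fit, trials, caliper = 0.05, within_trial = TRUE) {
  if (!is.numeric(caliper) || caliper <= 0) stop("caliper must be > 0")
  scores <- if (inherits(fit, "propensity_fit")) fit$scores else as.numeric(fit)
  tr <- data.table::as.data.table(trials)
  if (length(scores) != nrow(tr))
    stop("scores and patient-trial table have different lengths")
  tr <- data.table::copy(tr)
  tr$.score <- scores
  tr$.row <- seq_len(nrow(tr))
  groups <- if (within_trial) split(seq_len(nrow(tr)), tr$trial_id)
            else list(seq_len(nrow(tr)))

  pair_list <- lapply(groups, function(rows) {
    g <- tr[rows]
    it <- which(g$arm == "initiator")
    ct <- which(g$arm != "initiator")
    if (!length(it) || !length(ct)) return(NULL)
    m <- greedy_match_core(g$.score[it], g$.score[ct], caliper,
                           order_ids = g$pt_id[it] %||% seq_along(it))
    if (!nrow(m)) return(NULL)
    data.table::data.table(
      trial_id = g$trial_id[it[m$i]],
      init_row = g$.row[it[m$i]], ctrl_row = g$.row[ct[m$j]],
      init_pt_id = g$pt_id[it[m$i]], ctrl_pt_id = g$pt_id[ct[m$j]],
      init_patient_id = g$patient_id[it[m$i]],
      ctrl_patient_id = g$patient_id[ct[m$j]],
      score_init = g$.score[it[m$i]], score_ctrl = g$.score[ct[m$j]])
  })
  pairs <- data.table::rbindlist(pair_list[!vapply(pair_list, is.null, TRUE)])
  if (!nrow(pairs)) {
    pairs <- data.table::data.table(trial_id = integer(0), init_row = integer(0),
                                    ctrl_row = integer(0), init_pt_id = integer(0),
                                    ctrl_pt_id = integer(0),
                                    init_patient_id = integer(0),
                                    ctrl_patient_id = integer(0),
                                    score_init = numeric(0),
                                    score_ctrl = numeric(0))
  }
  pairs$distance <- abs(pairs$score_init - pairs$score_ctrl)
  pairs$pair_id <- seq_len(nrow(pairs))

  matched_rows <- c(rbind(pairs$init_row, pairs$ctrl_row))
  mt <- tr[matched_rows]
  mt$pair_id <- rep(pairs$pair_id, each = 2L)
  mt$.score <- NULL; mt$.row <- NULL
  structure(list(pairs = pairs, caliper = caliper, trials = mt),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort>", nrow(x$pairs), "pairs, caliper", x$caliper, "\n")
  invisible(x)
}

# Greedy core on one group: initiators in descending score order each take
# the closest unused control within the caliper. Sorted controls are kept in
# a doubly-linked list for amortised O(n log n) nearest-unused lookups.
# Distance ties go to the lower-score control; equal-score ties to the
# smaller control unit id (so the result is fully deterministic).
greedy_match_core <- function(s_init, s_ctrl, caliper, order_ids = NULL) {
  n <- length(s_init); m <- length(s_ctrl)
  if (is.null(order_ids)) order_ids <- seq_len(n)
  ord_i <- order(-s_init, order_ids)
  ord_c <- order(s_ctrl, seq_len(m))
  sc <- s_ctrl[ord_c]
  prv <- seq_len(m) - 1L          # 0 = before first
  nxt <- seq_len(m) + 1L          # m + 1 = past last
  used <- logical(m)
  prev_unused <- function(p) { while (p >= 1L && used[p]) p <- prv[p]; p }
  next_unused <- function(p) { while (p <= m && used[p]) p <- nxt[p]; p }
  res_i <- integer(0); res_j <- integer(0)
  for (ii in ord_i) {
    s <- s_init[ii]
    left <- prev_unused(findInterval(s, sc))
    right <- next_unused(if (left == 0L) 1L else nxt[left])
    dl <- if (left >= 1L) s - sc[left] else Inf
    dr <- if (right <= m) sc[right] - s else Inf
    dist <- min(dl, dr)
    if (!is.finite(dist) || dist > caliper) next
    anchor <- if (dl <= dr) left else right   # ties: lower score wins
    # among unused controls sharing the anchor's score, take the smallest id
    pick <- anchor
    p <- prev_unused(prv[anchor])
    while (p >= 1L && sc[p] == sc[anchor]) {
      if (ord_c[p] < ord_c[pick]) pick <- p
      p <- prev_unused(prv[p])
    }
    p <- next_unused(nxt[anchor])
    while (p <= m && sc[p] == sc[anchor]) {
      if (ord_c[p] < ord_c[pick]) pick <- p
      p <- next_unused(nxt[p])
    }
    used[pick] <- TRUE
    if (prv[pick] >= 1L) nxt[prv[pick]] <- nxt[pick]
    if (nxt[pick] <= m) prv[nxt[pick]] <- prv[pick]
    res_i <- c(res_i, ii); res_j <- c(res_j, ord_c[pick])
  }
  data.table::data.table(i = res_i, j = res_j)
}
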