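#' Bootstrap configuration
#'
#' @param replicates number of bootstrap resamples (default 300).
#' @param seed integer seed; identical configurations give identical CIs.
#' @param unit resampling unit. `"individual_within_pairs"` (default)
#'   resamples unique initiating individuals, so all matched pairs arising
#'   from one person travel together (both pair members always travel
#'   together); `"matched_pair"` resamples pairs independently.
#' @param levels percentile levels for the interval (default 2.5 / 97.5).
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(replicates = 300L, seed = 1L,
                             unit = c("individual_within_pairs", "matched_pair"),
                             levels = c(2.5, 97.5)) {
  unit <- match.arg(unit)
  if (replicates < 2L) stop("replicates must be >= 2")
  if (any(levels <= 0 | levels >= 100)) stop("percentile levels must lie in (0,100)")
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 unit = unit, levels = sort(levels) / 100),
            class = "bootstrap_config")
}

#' Percentile bootstrap CIs by resampling within the matched cohort
#'
#' For each replicate, matching units are resampled with replacement
#' (matched pairs, or unique initiating individuals whose pairs all travel
#' together), the pooled logistic model is refitted on the resampled
#' person-time, and the cumulative-incidence contrast is recomputed at each
#' horizon. Refitting uses replication weights, which gives exactly the
#' same likelihood as stacking the resampled person-intervals. Percentile
#' bounds are taken for each statistic; NNT/NNH bounds are the reciprocals
#' of the risk-difference percentile bounds.
#'
#' @param intervals matched person-interval table (from
#'   [expand_person_time()] on a matched cohort) carrying `pair_id`.
#' @param pairs the `pairs` table of the [greedy_match()] cohort (used to
#'   cluster pairs by initiating individual), or a `matched_cohort`.
#' @param estimand `"itt"` or `"pp"`.
#' @param horizons horizons in months at which effects are reported.
#' @param config a [bootstrap_config()].
#' @param keep_replicates keep the per-replicate statistics for audit.
#' @return list of class `bootstrap_effects`: one CI-augmented
#'   [effect_at()] estimate per horizon (`$ci` holds percentile bounds for
#'   risks, RR, RD and NNT/NNH plus the effective replicate count), the
#'   failure count, and optionally the replicate draws.
#' @export
bootstrap_ci <- function(intervals, pairs, estimand = c("itt", "pp"),
                         horizons = c(60L, 120L), config = bootstrap_config(),
                         keep_replicates = FALSE) {
  estimand <- match.arg(estimand)
  if (inherits(pairs, "matched_cohort")) pairs <- pairs$pairs
  pi <- data.table::as.data.table(intervals)
  if (!"pair_id" %in% names(pi))
    stop("intervals must carry a pair_id column (expand matched trials with ",
         "carry = \"pair_id\")")
  if (any(horizons %% 3 != 0)) stop("horizons must be multiples of 3 months")

  regimes <- if (estimand == "itt") c("initiator", "non-initiator")
             else c("always-treated", "never-treated")
  fit_fun <- if (estimand == "itt") fit_itt else fit_pp
  full <- fit_fun(pi)
  max_t <- max(pi$t_months)
  curves <- lapply(regimes, function(r)
    cumulative_incidence(full, r, max(horizons), observed_max_t = max_t))
  point <- lapply(horizons, function(h)
    effect_at(curves[[1]], curves[[2]], h, estimand = toupper(estimand)))

  # design built once; replicate weights only reweight the same rows
  A <- as.integer(pi$arm == "initiator")
  X <- if (estimand == "itt") itt_design(pi$t_months, A)
       else pp_design(pi$t_months, pi$cum_exposed_months)
  y <- pi$event
  t_grid <- seq(0L, max(horizons) - 3L, by = 3L)
  Xg <- lapply(regimes, function(r) {
    if (estimand == "itt") {
      a <- as.integer(r == "initiator")
      itt_design(t_grid, rep(a, length(t_grid)))
    } else {
      d <- if (r == "always-treated") t_grid else rep(0, length(t_grid))
      pp_design(t_grid, d)
    }
  })

  cluster_of_pair <- if (config$unit == "matched_pair") pairs$pair_id
                     else pairs$init_patient_id
  clusters <- unique(cluster_of_pair)
  pair_cluster_idx <- match(cluster_of_pair, clusters)
  row_pair_idx <- match(pi$pair_id, pairs$pair_id)

  hz_idx <- horizons %/% 3L
  set.seed(config$seed)
  B <- config$replicates
  draws <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    take <- sample.int(length(clusters), replace = TRUE)
    n_cl <- tabulate(take, nbins = length(clusters))
    w_pair <- n_cl[pair_cluster_idx]
    w <- w_pair[row_pair_idx]
    beta <- tryCatch(
      fast_logit(X, y, w, start = full$coefficients),
      error = function(e) NULL)
    if (is.null(beta)) { failures <- failures + 1L; next }
    risks <- lapply(Xg, function(M) {
      h <- stats::plogis(as.numeric(M %*% beta))
      cumsum_risk <- 1 - cumprod(1 - h)
      cumsum_risk[hz_idx]
    })
    r1 <- risks[[1]]; r0 <- risks[[2]]
    draws[[b]] <- c(r1 = r1, r0 = r0, rr = r1 / r0, rd = 100 * (r1 - r0))
  }
  if (failures > 0.1 * B)
    stop(sprintf("bootstrap estimator failed in %d of %d replicates", failures, B))
  mat <- do.call(rbind, draws[!vapply(draws, is.null, TRUE)])

  nh <- length(horizons)
  out <- vector("list", nh)
  for (j in seq_len(nh)) {
    q <- function(col) unname(stats::quantile(mat[, col], probs = config$levels))
    i <- if (nh == 1L) "" else as.character(j)
    col <- function(stem) if (nh == 1L) stem else paste0(stem, j)
    rd_b <- q(col("rd"))
    nnt_b <- sort(round(1 / pmax(abs(rd_b / 100), .Machine$double.eps)))
    est <- point[[j]]
    est$ci <- list(risk1 = 100 * q(col("r1")), risk0 = 100 * q(col("r0")),
                   rr = q(col("rr")), rd = rd_b, nnt = nnt_b,
                   replicates = nrow(mat), failures = failures)
    out[[j]] <- est
  }
  names(out) <- paste0("m", horizons)
  structure(list(estimates = out, estimand = estimand,
                 replicates = nrow(mat), failures = failures,
                 config = config,
                 draws = if (keep_replicates) mat else NULL),
            class = "bootstrap_effects")
}

#' @export
print.bootstrap_effects <- function(x, ...) {
  cat("<bootstrap_effects>", toupper(x$estimand), "estimand,",
      x$replicates, "replicates")
  if (x$failures) cat(" (", x$failures, " failed)", sep = "")
  cat("\n")
  for (e in x$estimates) print(e)
  invisible(x)
}
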