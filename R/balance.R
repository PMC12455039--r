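#' Standardized mean difference between arms
#'
#' Continuous covariates use `(mean1 - mean0) / sqrt((var1 + var0)/2)`;
#' binary covariates (or categorical levels as indicators) use
#' `(p1 - p0) / sqrt((p1(1-p1) + p0(1-p0))/2)`. Group 1 is the treated arm.
#' A pooled variance of zero with unequal means signals a degenerate
#' covariate.
#'
#' @param x1,x0 covariate values in the treated and comparator arm.
#' @param type `"continuous"` or `"binary"`; defaults to binary when the
#'   values take at most two distinct levels.
#' @return the standardized mean difference (0 when both arms are
#'   identically distributed with zero pooled variance).
#' @export
standardized_mean_difference <- function(x1, x0, type = NULL) {
  if (length(x1) < 2L || length(x0) < 2L)
    stop("need at least two units per arm")
  if (is.null(type)) {
    type <- if (length(unique(c(x1, x0))) <= 2L) "binary" else "continuous"
  }
  type <- match.arg(type, c("continuous", "binary"))
  if (type == "binary") {
    p1 <- mean(as.numeric(x1)); p0 <- mean(as.numeric(x0))
    pooled <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    num <- p1 - p0
  } else {
    num <- mean(x1) - mean(x0)
    pooled <- (stats::var(x1) + stats::var(x0)) / 2
  }
  if (pooled == 0) {
    if (abs(num) > 0)
      stop("degenerate covariate: zero pooled variance with unequal means")
    return(0)
  }
  num / sqrt(pooled)
}

#' Covariate balance table before and after matching
#'
#' Computes per-covariate standardized mean differences between initiators
#' and non-initiators in the full patient-trial table and in the matched
#' cohort. Categorical covariates are reported one row per level, as
#' indicator variables.
#'
#' @param trials full patient-trial table (before matching).
#' @param matched a `matched_cohort` from [greedy_match()] (or its
#'   `$trials` table).
#' @param covariates covariate column names to report.
#' @return `data.table` with columns `covariate`, `level` (NA for
#'   non-categorical), `smd_before`, `smd_after`.
#' @export
balance_table <- function(trials, matched, covariates) {
  tr <- data.table::as.data.table(trials)
  mt <- if (inherits(matched, "matched_cohort")) matched$trials else
    data.table::as.data.table(matched)
  one_side <- function(tab, cv, lev) {
    x1 <- tab[[cv]][tab$arm == "initiator"]
    x0 <- tab[[cv]][tab$arm != "initiator"]
    if (!is.null(lev)) {
      standardized_mean_difference(as.numeric(x1 == lev), as.numeric(x0 == lev),
                                   "binary")
    } else {
      standardized_mean_difference(as.numeric(x1), as.numeric(x0))
    }
  }
  rows <- list()
  for (cv in covariates) {
    x <- tr[[cv]]
    if (is.numeric(x)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        covariate = cv, level = NA_character_,
        smd_before = one_side(tr, cv, NULL), smd_after = one_side(mt, cv, NULL))
    } else {
      for (lev in sort(unique(as.character(x)))) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          covariate = cv, level = lev,
          smd_before = one_side(tr, cv, lev), smd_after = one_side(mt, cv, lev))
      }
    }
  }
  data.table::rbindlist(rows)
}
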