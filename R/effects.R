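#' Effect measures at a horizon
#'
#' Contrasts two cumulative-incidence curves at a stated horizon and
#' returns the absolute risks (percent), risk ratio, risk difference
#' (percentage points) and the number needed to treat or harm. The risk
#' ratio is the full-precision ratio of the risks (rounding happens only at
#' presentation); NNT/NNH is the nearest integer of the reciprocal absolute
#' risk difference on the proportion scale, labelled NNH when the treated
#' risk is higher and NNT when it is lower.
#'
#' `effect_from_risks()` performs the same arithmetic directly on a pair of
#' percent risks (e.g. risks read from a published effect table).
#'
#' @param curve1,curve0 curves from [cumulative_incidence()] for the
#'   treated and comparator regime (shared grid).
#' @param horizon_months horizon at which to read the risks; must be a grid
#'   point of both curves.
#' @param outcome optional outcome label carried into the estimate.
#' @param estimand `"ITT"` or `"PP"` label.
#' @return an object of class `effect_estimate`: `risk1`, `risk0` (percent),
#'   `rr`, `rd` (percentage points), `nnt` (with `nnt_label` `"NNT"` or
#'   `"NNH"`), `horizon_months`, and labels. `rr` is `NA` (with a warning)
#'   when the comparator risk is zero; `nnt` is `Inf` when the risks
#'   coincide.
#' @export
effect_at <- function(curve1, curve0, horizon_months, outcome = NA_character_,
                      estimand = NA_character_) {
  r1 <- curve1$risk[match(horizon_months, curve1$t_months)]
  r0 <- curve0$risk[match(horizon_months, curve0$t_months)]
  if (is.na(r1) || is.na(r0))
    stop("horizon is not a grid point of both curves")
  effect_from_risks(100 * r1, 100 * r0, horizon_months = horizon_months,
                    outcome = outcome, estimand = estimand)
}

#' @rdname effect_at
#' @param risk1_pct,risk0_pct absolute risks in percent for the treated and
#'   comparator regime.
#' @export
effect_from_risks <- function(risk1_pct, risk0_pct, horizon_months = NA,
                              outcome = NA_character_,
                              estimand = NA_character_) {
  rd_pct <- risk1_pct - risk0_pct
  if (risk0_pct == 0 && risk1_pct > 0) {
    warning("comparator risk is zero: risk ratio undefined")
    rr <- NA_real_
  } else if (risk0_pct == 0) {
    rr <- 1
  } else {
    rr <- risk1_pct / risk0_pct
  }
  nnt <- if (rd_pct == 0) Inf else round(1 / abs(rd_pct / 100))
  structure(list(outcome = outcome, estimand = estimand,
                 horizon_months = horizon_months,
                 risk1 = risk1_pct, risk0 = risk0_pct,
                 rr = rr, rd = rd_pct,
                 nnt = nnt,
                 nnt_label = if (rd_pct > 0) "NNH" else "NNT"),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  hz <- if (is.na(x$horizon_months)) "" else
    sprintf(" at %g months", x$horizon_months)
  cat(sprintf("<effect_estimate>%s%s%s\n",
              ifelse(is.na(x$outcome), "", paste0(" ", x$outcome)),
              ifelse(is.na(x$estimand), "", paste0(" [", x$estimand, "]")), hz))
  cat(sprintf("  risks %.2f%% vs %.2f%%; RR %.2f; RD %.2f pp; %s %s\n",
              x$risk1, x$risk0, x$rr, x$rd, x$nnt_label,
              ifelse(is.finite(x$nnt), format(x$nnt), "undefined (equal risks)")))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI: RR %.2f-%.2f; RD %.2f-%.2f pp (%d bootstrap replicates)\n",
                x$ci$rr[1], x$ci$rr[2], x$ci$rd[1], x$ci$rd[2],
                x$ci$replicates))
  }
  invisible(x)
}

#' Treatment-by-subgroup interaction in the intention-to-treat model
#'
#' Refits the pooled logistic intention-to-treat model with a subgroup main
#' effect and subgroup-by-treatment interaction terms and performs a Wald
#' test of the interaction. Per-subgroup effect estimates at the requested
#' horizon are computed from separate fits within each level.
#'
#' @param intervals matched person-interval table carrying the subgroup
#'   column (a baseline variable, e.g. sex or an age band).
#' @param subgroup name of the subgroup column.
#' @param horizon_months horizon for the per-level effect estimates.
#' @return list of class `subgroup_test`: `p_value`, `statistic`, `df`,
#'   and `estimates` (one [effect_at()] result per subgroup level).
#' @export
subgroup_interaction <- function(intervals, subgroup, horizon_months = 120L) {
  pi <- data.table::as.data.table(intervals)
  if (!subgroup %in% names(pi)) stop("subgroup column not found: ", subgroup)
  g <- factor(pi[[subgroup]])
  if (nlevels(droplevels(g)) < 2L)
    stop("subgroup must have at least two observed levels")
  g <- droplevels(g)
  A <- as.integer(pi$arm == "initiator")
  df <- data.frame(event = pi$event, A = A, t = pi$t_months, g = g)
  fit <- stats::glm(event ~ A + t + I(t^2) + A:t + g + A:g, data = df,
                    family = stats::binomial(), model = FALSE, y = FALSE)
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  ia <- grep("^A:g", names(cf))
  if (!length(ia)) stop("interaction terms were aliased; check the subgroup")
  b <- cf[ia]
  W <- as.numeric(t(b) %*% solve(vc[ia, ia, drop = FALSE]) %*% b)
  p <- stats::pchisq(W, df = length(ia), lower.tail = FALSE)

  ests <- lapply(levels(g), function(lev) {
    sub <- pi[g == lev]
    f <- fit_itt(sub)
    mx <- max(sub$t_months)
    c1 <- cumulative_incidence(f, "initiator", horizon_months, observed_max_t = mx)
    c0 <- cumulative_incidence(f, "non-initiator", horizon_months,
                               observed_max_t = mx)
    effect_at(c1, c0, horizon_months, outcome = lev, estimand = "ITT")
  })
  names(ests) <- levels(g)
  structure(list(p_value = p, statistic = W, df = length(ia),
                 subgroup = subgroup, estimates = ests),
            class = "subgroup_test")
}

#' @export
print.subgroup_test <- function(x, ...) {
  cat(sprintf("<subgroup_test> %s: Wald chi-square %.3f on %d df, p = %.4f\n",
              x$subgroup, x$statistic, x$df, x$p_value))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %s: RR %.2f (risks %.2f%% vs %.2f%%)\n", nm, e$rr,
                e$risk1, e$risk0))
  }
  invisible(x)
}
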