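#' Pooled logistic discrete-time hazard models
#'
#' `fit_itt()` fits the intention-to-treat hazard model on matched
#' person-time: event on a treatment-arm indicator `A`, time in months `t`,
#' its square, and the `A x t` interaction (allowing nonproportional
#' hazards). `fit_pp()` fits the per-protocol dose-response model: the arm
#' indicator is replaced by cumulative exposed months `d` (and its square)
#' measured at interval entry, alongside the same time terms. Time is
#' months since the index date evaluated on the 3-month grid
#' (`t = 0, 3, 6, ...`).
#'
#' With `time = "saturated"` the quadratic time trend is replaced by one
#' indicator per observed interval (crossed with the arm when both arms are
#' present); the fitted hazards are then the empirical per-interval event
#' proportions, which makes the model-based cumulative incidence coincide
#' with the discrete-time product-limit estimator.
#'
#' @param intervals person-interval table from [expand_person_time()]
#'   (needs `event`, `t_months`, and `arm` for `fit_itt()` /
#'   `cum_exposed_months` for `fit_pp()`).
#' @param time `"quadratic"` (default) or `"saturated"`.
#' @return an object of class `pooled_logit_fit` with elements
#'   `estimand` (`"itt"` or `"pp"`), `coefficients`, `vcov`, `n_intervals`,
#'   `n_events`, `converged` and, for per-protocol fits, `dose_estimable`.
#' @name hazard_models
NULL

#' @rdname hazard_models
#' @export
fit_itt <- function(intervals, time = c("quadratic", "saturated")) {
  time <- match.arg(time)
  pi <- data.table::as.data.table(intervals)
  if (!sum(pi$event)) stop("no events in the person-interval table")
  A <- as.integer(pi$arm == "initiator")
  two_arms <- length(unique(A)) == 2L
  t_levels <- if (time == "saturated") sort(unique(pi$t_months)) else NULL
  X <- itt_design(pi$t_months, A, time, t_levels, two_arms)
  fit <- fit_pooled(X, pi$event)
  structure(c(fit, list(estimand = "itt", time = time, t_levels = t_levels,
                        two_arms = two_arms)),
            class = "pooled_logit_fit")
}

#' @rdname hazard_models
#' @export
fit_pp <- function(intervals, time = c("quadratic", "saturated")) {
  time <- match.arg(time)
  pi <- data.table::as.data.table(intervals)
  if (!sum(pi$event)) stop("no events in the person-interval table")
  d <- pi$cum_exposed_months
  dose_estimable <- length(unique(d)) >= 2L
  if (all(d == 0)) {
    warning("no exposed person-time: dose coefficients are inestimable; ",
            "fitting the baseline-hazard model only")
    dose_estimable <- FALSE
  }
  t_levels <- if (time == "saturated") sort(unique(pi$t_months)) else NULL
  X <- pp_design(pi$t_months, d, time, t_levels, dose = dose_estimable)
  fit <- fit_pooled(X, pi$event)
  structure(c(fit, list(estimand = "pp", time = time, t_levels = t_levels,
                        dose_estimable = dose_estimable)),
            class = "pooled_logit_fit")
}

#' @export
print.pooled_logit_fit <- function(x, ...) {
  cat("<pooled_logit_fit>", toupper(x$estimand), "model,", x$time, "time;",
      x$n_intervals, "person-intervals,", x$n_events, "events\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# -- design matrices (shared with the bootstrap fast path) -------------------

itt_design <- function(t, A, time = "quadratic", t_levels = NULL,
                       two_arms = TRUE) {
  if (time == "quadratic") {
    X <- cbind(`(Intercept)` = 1, A = A, t = t, t2 = t^2, A_t = A * t)
    if (!two_arms) X <- X[, c("(Intercept)", "t", "t2"), drop = FALSE]
    return(X)
  }
  tf <- factor(t, levels = t_levels)
  df <- data.frame(tf = tf)
  if (two_arms) {
    df$A <- A
    stats::model.matrix(~ A * tf, df)
  } else {
    stats::model.matrix(~ tf, df)
  }
}

pp_design <- function(t, d, time = "quadratic", t_levels = NULL, dose = TRUE) {
  if (time == "quadratic") {
    X <- cbind(`(Intercept)` = 1, t = t, t2 = t^2, d = d, d2 = d^2)
    if (!dose) X <- X[, c("(Intercept)", "t", "t2"), drop = FALSE]
    return(X)
  }
  base <- stats::model.matrix(~ tf, data.frame(tf = factor(t, levels = t_levels)))
  if (dose) cbind(base, d = d, d2 = d^2) else base
}

fit_pooled <- function(X, y, weights = NULL, start = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = weights, family = stats::binomial(),
                   start = start,
                   control = stats::glm.control(maxit = 50)))
  if (!fit$converged) stop("pooled logistic model did not converge")
  cf <- fit$coefficients
  if (anyNA(cf))
    stop("pooled logistic design is rank deficient (aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), ")")
  if (any(abs(cf) > 30))
    stop("separation in the pooled logistic model (diverging coefficient: ",
         names(cf)[which.max(abs(cf))], ")")
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  dimnames(covmat) <- list(names(cf), names(cf))
  list(coefficients = cf, vcov = covmat,
       n_intervals = length(y), n_events = sum(y * weights),
       converged = fit$converged)
}

# Newton-Raphson weighted logistic MLE. Identical optimum to glm.fit but
# without its per-call overhead; used for the bootstrap refits, where the
# design matrix is fixed and only replication weights change.
fast_logit <- function(X, y, w, start, maxit = 25L, tol = 1e-8) {
  beta <- start
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    grad <- crossprod(X, w * (y - mu))
    H <- crossprod(X, X * (w * mu * (1 - mu)))
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (!all(is.finite(beta))) stop("diverging logistic fit")
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) break
  }
  if (any(abs(beta) > 30)) stop("separation in bootstrap logistic refit")
  beta
}

# Hazard on the 3-month grid under a counterfactual regime.
hazard_on_grid <- function(fit, regime, t_grid) {
  if (fit$estimand == "itt") {
    A <- as.integer(regime %in% c("initiator", "always-treated", "treated"))
    if (!fit$two_arms && A == 1)
      stop("single-arm fit cannot predict the treated regime")
    X <- itt_design(t_grid, rep(A, length(t_grid)), fit$time, fit$t_levels,
                    fit$two_arms)
  } else {
    always <- regime %in% c("always-treated", "initiator", "treated")
    if (always && isFALSE(fit$dose_estimable))
      stop("dose coefficients were inestimable; cannot predict sustained treatment")
    d <- if (always) t_grid else rep(0, length(t_grid))
    X <- pp_design(t_grid, d, fit$time, fit$t_levels,
                   dose = !isFALSE(fit$dose_estimable))
  }
  if (!setequal(colnames(X), names(fit$coefficients)))
    stop("prediction grid contains time points outside the fitted levels")
  as.numeric(stats::plogis(X[, names(fit$coefficients), drop = FALSE] %*%
                             fit$coefficients))
}

#' Model-based cumulative incidence under a static regime
#'
#' Compounds the fitted per-interval discrete hazards into a cumulative
#' incidence curve: `risk(T) = 1 - prod_{k: 3k < T} (1 - h(3k, regime))` on
#' the 3-month grid. For intention-to-treat fits the regimes are
#' `"initiator"` / `"non-initiator"` (arm indicator fixed at 1 or 0); for
#' per-protocol fits `"always-treated"` (cumulative exposure equal to time
#' since baseline) / `"never-treated"` (zero throughout).
#'
#' @param fit a [fit_itt()] or [fit_pp()] result.
#' @param regime regime label, see Details.
#' @param horizon_months last time point of the curve; multiple of 3.
#' @param observed_max_t largest `t_months` in the fitting data, if known;
#'   predictions beyond it raise an extrapolation warning.
#' @return `data.table` with `t_months` (0, 3, ..., horizon), nondecreasing
#'   `risk` starting at 0, and the `regime` label.
#' @export
cumulative_incidence <- function(fit, regime, horizon_months,
                                 observed_max_t = NULL) {
  if (horizon_months %% 3 != 0) stop("horizon_months must be a multiple of 3")
  t_grid <- seq(0L, horizon_months - 3L, by = 3L)
  max_fit_t <- observed_max_t %||%
    (if (!is.null(fit$t_levels)) max(fit$t_levels) else NULL)
  if (!is.null(max_fit_t) && max(t_grid) > max_fit_t)
    warning("horizon extends beyond observed follow-up (extrapolation)")
  h <- hazard_on_grid(fit, regime, t_grid)
  risk <- 1 - cumprod(1 - h)
  data.table::data.table(t_months = c(0L, t_grid + 3L), risk = c(0, risk),
                         regime = regime)
}
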