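---
title: "Sequential target-trial emulation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential target-trial emulation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtte)
```

## The problem

Observational drug-safety questions of the form "does initiating drug X
change the risk of outcome Y?" are prone to immortal-time and prevalent-user
bias when analysed naively. Target trial emulation avoids both by writing
down the protocol of the randomized trial one would have run — eligibility,
time zero, treatment strategies, follow-up, estimands — and aligning the
observational analysis with it. The sequential variant re-runs the emulated
trial on a dense grid of time points (here every 3 months of attained age,
or of calendar time), so one person can enter many trials while eligible.
The unit of analysis is therefore the *patient-trial*.

`seqtte` implements that pipeline end to end for longitudinal
health-record tables, together with a synthetic record generator whose
causal structure is fully known, so that each stage can be validated by
parameter recovery against closed-form oracles rather than by eyeballing.

## The estimation machinery

**Eligibility and time zero.** At each trial point, a patient is eligible
if they carry the index condition, fall in the age window, are registered
and alive, have no history of any exclusion condition or drug, and pass a
365-day study-drug washout (the new-user condition). The washout window is
open on both sides: a prescription dated exactly on the index date is an
initiation event, not a washout violation — an initiation cannot be its own
exclusion. Attained-age index dates use exact calendar arithmetic from the
birth date (months added with day-of-month clamping), so "the day the
patient turns 62.25 years" is a well-defined date.

**Arms.** The arm is fixed at baseline by the first-3-months rule: a
patient-trial is an *initiator* iff at least one study-drug prescription
falls in `[index, index + 91 days)`. Later initiation never changes the
arm; it is handled by the per-protocol dose model.

**Discrete person-time.** Follow-up is cut into 91-day intervals
(`t = 3k` months). Within an interval the terminal precedence is
outcome > death > censoring; dates on a boundary belong to the later
interval. Death is handled per outcome as censoring (the default, a
controlled direct effect), as a terminal competing event, or as part of a
composite outcome. The dose clock `d` (cumulative exposed months)
increments by 3 for each exposed interval *before* the current one, so it
is predictable at interval entry and cannot leak same-interval
outcome-exposure feedback.

**Propensity scores and matching.** Initiation is modelled by logistic
regression on the baseline covariates, age excluded (the grid matches on
it exactly), continuous covariates entered linear + quadratic. Matching is
1:1 greedy nearest-neighbour without replacement within trial, caliper
0.05 on the probability scale, initiators processed in descending score
order. Ties in distance go to the lower-score control, and equal-score
ties to the smaller unit id, making the algorithm fully deterministic; a
brute-force enumeration oracle in the test suite confirms the optimized
implementation on every small instance. Balance is summarised by
standardized mean differences with the usual pooled-variance formulas and
the |SMD| < 0.1 convention.

**Pooled logistic hazard models.** On the matched person-time,
the intention-to-treat model is

$$\operatorname{logit} h(t, A) = \beta_0 + \beta_A A + \beta_1 t + \beta_2 t^2 + \beta_3 A t$$

and the per-protocol dose-response model replaces the arm indicator with
cumulative exposed months:

$$\operatorname{logit} h(t, d) = \gamma_0 + \gamma_1 t + \gamma_2 t^2 + \gamma_3 d + \gamma_4 d^2.$$

The interaction uses linear time only: the quadratic belongs to the
baseline time trend, and a single treatment-time product is what relaxes
proportional hazards. Fitted hazards compound into cumulative incidence by
the product formula $1 - \prod_k (1 - \hat h(3k, \cdot))$; the
counterfactual regimes set $A \in \{1, 0\}$ (ITT) or $d = t$ versus
$d = 0$ (always- versus never-treated). With time entered saturated (one
indicator per interval) the model-based curve equals the discrete
product-limit estimator exactly, which the tests assert. Effects at a
horizon are reported as percent risks, their ratio (full precision,
rounded only at presentation), the risk difference in percentage points,
and NNT/NNH as the nearest integer of the reciprocal risk difference.

**Bootstrap.** Percentile CIs come from 300 resamples. The default
resampling unit clusters matched pairs by the initiating individual — a
person contributing several patient-trials travels as one block, the
closest operational reading of "individual-level resampling within matched
pairs"; a plain pair-resampling mode is also provided, and neither mode is
claimed to replicate any specific published interval. Refits use
replication weights on a fixed design matrix, which has exactly the same
likelihood as stacking the resampled person-time but avoids rebuilding it;
a dedicated Newton solver makes the 300 refits cheap. NNT/NNH bounds are
the reciprocals of the risk-difference percentile bounds.

## The synthetic generator: what it emulates and what it does not

`sim_config()`/`generate_population()` produce the four record tables
(patients, diagnoses, prescriptions, covariate measurements) with known
causal structure:

* covariates are sampled once at registration (time-fixed), matching the
  baseline-only covariate capture of the design;
* treatment initiation is a per-interval Bernoulli whose log-odds are a
  linear function of covariates — the confounding knob;
* exposure is sustained with a per-interval discontinuation probability,
  and re-initiation is possible (memoryless);
* the outcome and death are discrete-time hazards; current-interval
  exposure multiplies the outcome odds by `true_effect`;
* one prescription is emitted per exposed interval at the interval start,
  so "any prescription in the interval" is an exact exposure indicator,
  removing dose ambiguity on purpose;
* every outcome event emits a diagnosis plus two confirmatory
  prescriptions on distinct dates, so code-plus-two-prescriptions outcome
  definitions are exercised;
* administrative censoring happens at registration end.

The default parameters are the package's study conditions: registration
starting at ages 40-55 for 10-45 years; initiation log-odds intercept −4
(about 2-4% per 3-month interval once covariate effects are added, giving
a realistic minority of initiators); discontinuation 0.08 per interval
(roughly 70% one-year persistence); outcome hazard 0.004 per interval
(≈1.6%/year, a common-outcome rate that yields enough events for stable
estimation at the cohort sizes used); death hazard 0.003 per interval.

What the generator deliberately does **not** emulate: dependence among
covariates beyond what the confounding coefficients induce, realistic
disease natural history or dosing, clinical code dictionaries (codes are
abstract strings), time-varying covariates (a hook exists in the design
but baseline capture is what the analysis uses), and linkage artefacts
such as duplicate registrations. Passing tests therefore demonstrate that
the *machinery* is correct under known structure — not that any real-world
confounding pattern is fully adjustable.

`true_marginal_risk()` is the ground-truth oracle: the exact product over
interval hazards under always/never-treated, marginalised over the
covariate distribution by exhaustive enumeration when all outcome-relevant
covariates are binary, otherwise by Monte Carlo with the replicate count
recorded on the result. It ignores death, i.e. it is the net
(cause-specific) risk that a hazard model with death treated as censoring
targets.

## Why the dose model is validated on a matched cohort

The generator's truth is a *current-exposure* odds ratio, while the
per-protocol model is quadratic in *cumulative* dose — a deliberate
misspecification mirroring the applied analysis. On an unmatched cohort
with staggered initiation the share of exposed person-time grows with
time since baseline, so the free time terms absorb most of the exposure
effect and the always-versus-never contrast is attenuated by roughly 20%.
On a 1:1 matched new-user cohort both regimes are represented at every
interval, the exposed share is roughly constant in time, and the dose
terms are identified. This is also how the applied analysis uses the
model (it is fitted on the matched person-time), and it is why the
recovery tests construct a matched cohort first. A residual attenuation
of roughly −8% remains even then — a quadratic cannot represent a
step-shaped exposure effect, and imperfect adherence freezes the dose
clock for ex-users at mid-range doses — and it is the main known
limitation of the dose-response estimand. The recovery tests therefore
assert the *mean* signed relative error over several seeded replicates,
which estimates this bias with the per-replicate Monte-Carlo noise
averaged out, rather than gating on a single noisy draw.

A related choice: the per-protocol predictions use the matched-cohort
model without further covariate standardisation. Matching is the design's
confounding control; no claim is made that the predictions standardise
over any other covariate distribution.

## Numerical choices and degenerate inputs

* Logistic fits: `glm`/`glm.fit` maximum likelihood; coefficients beyond
  ±30 or fitted probabilities within 1e−8 of 0/1 are treated as
  separation and raised as errors naming the worst term; bootstrap refits
  use a Newton solver warm-started at the full-data fit, and replicates
  that fail are dropped and counted (more than 10% failures aborts).
* Zero pooled variance with unequal means in an SMD is an error
  (degenerate covariate); with equal means the SMD is 0.
* An all-unexposed cohort makes the dose coefficients inestimable: the fit
  downgrades to the baseline-hazard model with a warning and refuses to
  predict the always-treated regime.
* A comparator risk of exactly zero makes the risk ratio `NA` with a
  warning; equal risks give an infinite NNT, reported as such.
* Horizons must lie on the 3-month grid; predicting beyond observed
  follow-up warns about extrapolation.
* All randomness flows from explicit seeds; identical configurations
  reproduce byte-identical datasets and intervals.

## Problem sizes used by the tests and the acceptance script

The reported simulations use reduced age grids (the grid span is a free
design parameter, and a narrower span exercises the same sequential
structure at a fraction of the cost of the full 140-trial 50-84 grid):
null-effect coverage uses 20 cohorts of 5,000 patients on a 20-trial
grid (ages 60-64) with 300 bootstrap resamples each; dose-response
recovery uses cohorts of 30,000 patients on a 40-trial grid (ages
58-67), yielding about 10,700 matched patient-trials per seed, with the
mean relative error over six seeds compared against the oracle; balance
recovery uses 40 replicates of 5,000 confounded patient-trials.
The worked example in `analysis/` uses 20,000 patients on a 40-trial
grid. These sizes were chosen so that Monte-Carlo standard errors are
comfortably inside the tolerances being asserted.

## Known limitations

* The dose-response estimand inherits the attenuation described above
  when adherence is poor; it is a feature of the model family, not of the
  implementation.
* Competing death is handled by censoring, composite outcomes or
  competing-event bookkeeping only; no subdistribution-hazard estimator is
  provided.
* The generator's covariates are independent given the configured
  coefficients; real record data are not.
* Matching is 1:1 without replacement within trial; variable-ratio and
  weighting estimators are out of scope.
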