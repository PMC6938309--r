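---
title: "Modelling transitions into and out of alcohol use disorder with two-state panel Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transitions into and out of alcohol use disorder with two-state panel Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audmc)
```

## The model

`audmc` models a binary alcohol-use-disorder (AUD) state observed at
irregular panel assessments as a two-state continuous-time Markov chain.
Between the states No-AUD (0) and AUD (1), movement is governed by
transition intensities — instantaneous rates analogous to hazards in
survival analysis, but with movement allowed in both directions. Each
intensity depends log-linearly on the covariate vector $z$ measured at the
**earlier** assessment of a pair:

$$\log q_{01} = \alpha_{01} + \beta_{01}^\top z, \qquad
  \log q_{10} = \alpha_{10} + \beta_{10}^\top z,$$

where $q_{01}$ is the AUD *onset* intensity and $q_{10}$ the *remission*
intensity, both per month. Exponentiated coefficients are hazard ratios
(HRs): the multiplicative effect of a one-unit covariate increase on a
transition rate.

For a two-state generator $Q(z)$ the transition probability matrix over a
gap $\Delta t$ has a closed form. With $s = q_{01} + q_{10}$,

$$P_{00}(\Delta t) = \frac{q_{10} + q_{01} e^{-s\,\Delta t}}{s},$$

and the other entries follow by complement and symmetry
(`transition_matrix()`). The package also evaluates $P(\Delta t) =
e^{Q \Delta t}$ through a general matrix exponential
(`transition_matrix_expm()`), used only as an independent cross-check; the
two agree to below $10^{-10}$ across the rate and gap ranges the tests
sweep.

### The panel likelihood

The chain is observed only at assessment times ("panel data"): transition
times between assessments are never seen. Under the Markov assumption, each
consecutive pair of observed assessments contributes
$\log P_{s_0 s_1}(\Delta t;\ z_{\text{pre}})$, with the generator
evaluated at the pre-transition covariates and held constant across the
interval (covariates update at each observation, so inhomogeneity enters
piecewise). Missed waves need no special treatment: a subject observed at
months 0 and 12.7 contributes one pair with $\Delta t = 12.7$, with no
assumption about the skipped wave. `cohort_loglik()` sums the sorted
per-pair log-probabilities so the value does not depend on pair order.

### Constraints and state-dependence

A covariate effect is *state-independent* when its effect on the hazard of
future AUD does not depend on the current state, which in this
parameterization means $\beta_{01} = -\beta_{10}$. Constrained covariates
share a single parameter $\gamma$ with opposite signs, so their onset and
remission HRs are exact reciprocals — a structural identity, not an
estimate. `test_state_dependence()` tests the constraint with a
likelihood-ratio test (LRT) on the single-covariate model: twice the
log-likelihood difference between the unconstrained and constrained fits,
referred to $\chi^2_1$. An LRT was chosen over a Wald contrast because it
is invariant to parameterization; the choice is recorded in every run log.
The test is run on unadjusted single-covariate models (not inside the
joint model), and strictly single-covariate — demographics are not
co-fitted during testing.

### Model-building procedure

The staged procedure in `analyze_cohort()` mirrors the epidemiological
workflow the package targets:

1. Average the collinear anxiety and depression symptom scores into one
   internalizing score (`combine_covariates()`); the sources stay in the
   data for descriptives but leave the candidate list.
2. Stratify transition pairs at age 21 (legal drinking age), classifying
   each pair by its **pre-transition** age — consistent with the use of
   pre-transition covariates for pairs straddling the 21st birthday.
3. A covariate enters a stratum's model when either descriptive contrast
   (onset: No-AUD pairs that did vs did not transition; remission:
   AUD pairs likewise) is significant at 0.05; the demographic controls
   (age, sex, race, public assistance) enter regardless.
4. Constrain each entered covariate across states when its
   state-dependence p-value exceeds 0.20. The threshold is deliberately
   liberal: the constraint is only imposed when there is very little
   evidence against it, because imposing it wrongly nullifies the
   "transition" character of the model, while imposing it rightly recovers
   power lost to the age stratification.
5. Fit the adjusted joint model per stratum and report HRs with 95% Wald
   intervals; constrained rows are flagged with a dagger in rendered
   tables.

No multiplicity correction is applied across covariates, and no automated
variable selection occurs beyond the two stated rules.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sd_threshold` | 0.20 | p-value | liberal bar for constraining effects across states (see above) |
| `screen_alpha` | 0.05 | p-value | conventional entry screen on descriptive contrasts |
| `age_cutoff` | 21 | years | legal drinking age; the developmental boundary motivating stratification |
| `starts` | 3 | — | random restarts around the method-of-moments start |
| `B` | 1000 | iterations | parametric-bootstrap size for the lack-of-fit p-value |
| `min_expected` | 5 | count | smallest expected cell before groups collapse in the Pearson statistic |

Covariates are **not** standardized before fitting, so HRs are per
instrument unit (per ASSIST point, per year of age, ...); a
`standardize` toggle exists and maps estimates back to the per-unit scale
either way.

## Numerical choices

* **Parameterization.** Optimization runs unbounded over
  $(\alpha_{01}, \alpha_{10}, \beta\text{'s}, \gamma\text{'s})$;
  intensities are recovered by exponentiation, so positivity holds by
  construction and constraints are built into the parameter layout rather
  than imposed by the optimizer.
* **Optimizer.** BFGS with the *analytic* score of the panel likelihood
  (closed-form partials of the two-state $P(\Delta t)$, chained through
  $\partial q/\partial \theta = q\,x$). The analytic gradient makes the
  replicate-heavy calibration studies below practical and is verified
  against central finite differences in the test suite. The default start
  sets the intercepts to log crude rates (events over person-time at risk)
  with zero coefficients; additional starts are seeded
  $\mathcal N(0, 0.3)$ perturbations and the best converged solution is
  kept.
* **Covariance.** Inverse of the observed information, obtained by central
  finite differences of the analytic score at the optimum (step $10^{-3}$;
  because the differenced quantity is itself analytic, the resulting
  Hessian error is $O(10^{-6})$). A singular or indefinite information
  matrix falls back to a flagged pseudo-inverse with a warning.
* **Degenerate inputs.** Line searches that underflow a transition
  probability see a clamped value rather than an error (the strict
  positivity contract still applies to `cohort_loglik()` itself); constant
  covariates are flagged as unidentifiable; cohorts without transitions in
  one direction warn about weak intercept identification; pairs with
  missing covariates are dropped from fitting with a logged count rather
  than imputed, since the workflow describes no imputation.
* **Intercept reporting.** The raw intercepts are log-intensities at
  covariate zero — for this design roughly twenty years outside the
  cohort's age support — so their sampling error is dominated by amplified
  age-slope noise. Calibration checks therefore evaluate baseline
  intensities at the generator's reference covariate profile
  ($\alpha + \beta^\top z_{\mathrm{ref}}$), where the data actually live;
  coefficients are always assessed on the raw per-unit scale.

## The lack-of-fit test

`pearson_statistic()` partitions pairs by pre-state, tertile of the time
gap, and tertile of the fitted exit linear predictor; within each group the
expected count of each post-state is the sum of fitted probabilities
$P_{ij}(\Delta t; z)$, and $T = \sum (o - e)^2 / e$. Groups whose smallest
expected cell drops below 5 collapse into a neighbouring group of the same
pre-state. The grouping scheme is a package choice (configurable and
recorded in output); no exact asymptotic null is attempted for the grouped
statistic. Calibration is by parametric bootstrap
(`bootstrap_pvalue()`): post-states are re-simulated from the fitted model
conditional on each pair's observed pre-state, gap and covariates, the
model is refit to each replicate (toggleable; refitting is the default and
the honest choice, since the statistic is computed at an estimated
parameter), and $p = (1 + \#\{T_b \ge T_{\mathrm{obs}}\})/(B+1)$ — never
exactly zero by the add-one rule.

## What the synthetic cohort emulates — and what it does not

`cohort_spec()` / `generate_cohort()` stand in for a cohort that is not
publicly deposited. The generator reproduces the *design*: 599 subjects
aged 14–24 at baseline; five assessments at jittered ~6-month gaps;
independent 16.3% per-follow-up missingness (the complement of the
design's 83.7% retention floor); the baseline demographic mix (58.8% male,
58.3% Black, 73.0% public assistance); time-varying covariates as clamped
stationary AR(1) processes on their instrument scales (means and spreads
matching the magnitudes those instruments produce); and state paths drawn
wave-to-wave directly from the closed-form $P(\Delta t)$ at the earlier
wave's covariates — the exact marginal at observation times, which is all
the panel likelihood ever sees, so simulating latent event times would add
cost without changing any distribution the pipeline observes.

The `"paper_like"` preset uses the adjusted-model hazard ratios of the
emulated study as generating coefficients (e.g. cannabis constrained at
HR 1.18, male onset HR 2.28), with baseline intensities anchored so that
the cohort reproduces crude transition rates of roughly 0.0117 onsets and
0.093 remissions per person-month at the reference covariate profile —
the rates implied by the emulated study's transition tallies. A `"null"`
preset (no effects, symmetric intensities) and a `"state_dependent"`
preset (a cannabis effect of +0.5 on *both* transitions, maximally
violating the constraint null) support the calibration studies.

Deliberate non-goals: missingness is MCAR (the emulated design reports
only retention rates, so informative dropout is not modelled); covariate
processes reproduce marginal locations, spreads and persistence but not
the real cohort's joint dependence structure; and baseline AUD prevalence
(12%) is a design choice informed by the share of pre-AUD person-time.
Consequently, passing calibration tests demonstrates that the estimator,
the tests and the bootstrap behave correctly *under the model's own
assumptions and this design* — it does not validate the substantive
findings of any real cohort, whose hazard ratios are not reproducible
without the raw data.

## What the calibration studies check

All study sizes below are package choices balancing Monte Carlo error
against runtime, and run with fixed seeds.

* **Parameter recovery** — 100 cohorts of 599 subjects × 5 waves under the
  `"paper_like"` truth: every coefficient's mean estimate within ±0.1 of
  truth, reference-profile baseline intensities within ±0.1, pooled 95%
  Wald coverage within [90%, 99%].
* **Type-I error of the state-dependence LRT** — 500 cohorts generated
  with $\beta_{01} = -\beta_{10}$ exactly: rejection rate at
  $\alpha = 0.05$ within [0.03, 0.08] (observed ≈ 0.054).
* **Bootstrap calibration** — 50 cohorts of 250 subjects generated from
  the fitted family itself, bootstrap at $B = 200$: the p-values are
  compatible with uniformity (Kolmogorov–Smirnov at the 1% level).
* **Oracles** — closed form vs matrix exponential to $10^{-10}$; the panel
  likelihood vs hand-summed closed-form terms on toy cohorts to
  $10^{-12}$; the intercept-only MLE vs a brute-force likelihood grid.

## Known limitations

* Two states only; no absorbing state, no frailty or random effects, and
  no time-inhomogeneity beyond covariates updating at assessments.
* Descriptive contrasts treat person-transition pairs as independent
  units; a subject contributes several pairs and no clustering adjustment
  is applied (none is part of the emulated procedure).
* Wald intervals can misbehave for covariates with very few events in a
  stratum; the liberal constraint rule mitigates but does not remove this.
* The bootstrap refits each replicate with a single warm start; extremely
  small strata may need `starts > 1` at additional cost.
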