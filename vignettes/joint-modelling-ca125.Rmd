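---
title: "Joint modelling of CA-125 kinetics and the resectability decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of CA-125 kinetics and the resectability decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

In advanced ovarian cancer treated with neoadjuvant chemotherapy (NAC),
the decision whether a complete interval cytoreductive surgery is feasible
is made during treatment, on imaging and laparoscopy that both have known
blind spots. Serum CA-125 tracks tumour burden, and its *kinetics* under
chemotherapy — not any single value — carry information about how the
disease is responding. `ca125jm` implements a Bayesian joint model that
links the longitudinal CA-125 trajectory to the time of a resectable
decision, and turns the fitted model into patient-level *dynamic
predictions* that update as each new marker value arrives.

## Model

**Longitudinal sub-model.** CA-125 spans several orders of magnitude, so
the model works on $y = \log\sqrt{\mathrm{CA125}} = \tfrac12\log
\mathrm{CA125}$ (natural logarithm; the inverse is $\exp(2y)$). For
subject $i$ at time $t$ (weeks from the first NAC cycle),

$$y_{ij} = m_i(t_{ij}) + \varepsilon_{ij}, \qquad
  m_i(t) = (\beta_1 + b_{0i}) + (\beta_2 + b_{1i})\,t
         + \beta_3\,\mathrm{cycles}_i(t) + \beta_4\,\mathrm{para}_i(t),$$

with $b_i \sim N(0, D)$ a random intercept and slope and
$\varepsilon \sim N(0, \sigma^2)$. The cumulative number of completed
chemotherapy cycles and of paracenteses enter as time-varying step
functions: both demonstrably shift marker levels, and including them lets
the slope describe the treatment-free drift. Random intercept + slope is
the richest structure identifiable with 2–6 measurements per subject.
The standalone fit (`fit_lme()`) maximizes the exact Gaussian marginal
likelihood — maximum likelihood rather than REML, so the separate fit and
the joint model's longitudinal block share one objective. $\beta$ is
profiled out by generalized least squares and a BFGS search runs over the
Cholesky factor of $D$ and $\log\sigma$ (positivity without constraints;
relative-objective tolerance $10^{-8}$).

**Hazard sub-model.** Follow-up runs from the first cycle to the
operability decision; a *resectable* decision is the event and a
non-resectable decision is censoring at the same time. The standalone
screening model (`fit_cox()`, `univariate_screen()`) is a proportional
hazards partial likelihood with Efron tie handling (decision dates
cluster on meeting grids), Newton–Raphson with step-halving, Wald
intervals, and univariate screening at $p < 0.05$ to choose the
covariates that enter the joint model — by default performance status
(one linear term per unit, matching how a single hazard ratio per PS unit
is usually reported) and epigastric peritoneal carcinomatosis.

**Joint model.** The two parts are linked by the *current value* of the
noiseless trajectory:

$$h_i(t) = \lambda(t)\, \exp\{\gamma^\top w_i + \alpha\, m_i(t)\}.$$

The current-value association is the canonical choice when the biomarker
is read as a proxy of instantaneous tumour burden; slope or cumulative
associations are out of scope. $\lambda(t)$ is piecewise constant with
$K = 5$ pieces and knots at event-time quintiles — flexible, and each
piece admits a closed-form integral in the oracle tests. The cumulative
hazard is integrated exactly within each piece/covariate segment by
7-node Gauss–Legendre quadrature, cut additionally at every jump of the
cycle or paracentesis step function (the integrand is then
$\exp(\text{linear})$, for which the rule is accurate far below the
$10^{-10}$ tolerance asserted in the tests).

Between the last observed measurement and the decision time the covariate
paths are not observed; the package carries the observed cumulative
counts forward and then continues accruing cycles at the visit cadence up
to the baseline total. For cohorts generated by this package that
extension reproduces the generating path exactly; for arbitrary data it
is a stated convention.

**Priors.** Weakly informative throughout (no established prior information
exists for this setting): $N(0, 10^2)$ for $\beta, \gamma, \alpha$; half-$N(0,10)$ for
$\sigma$ and the random-effect SDs with a uniform correlation; and
$\Gamma(0.1, 0.1)$ for each baseline rate.

**Sampler.** Metropolis-within-Gibbs with componentwise adaptive
random-walk proposals (acceptance targets 0.40 for scalars, 0.25 for the
bivariate random-effect updates; Robbins–Monro adaptation during burn-in,
frozen afterwards). All $n$ random-effect vectors are updated in one
vectorized pass — valid because they are conditionally independent given
the parameters. Two extra moves repair the slow directions every joint
model has: a *translation* move that shifts $\beta_1$ (or $\beta_2$) and
all $b_{0i}$ (or $b_{1i}$) oppositely, leaving both likelihoods invariant
so only the priors decide; and a *ridge* move along the
$(\beta_2, \beta_3)$ trade-off created by cycles $\approx t/3$. Without
these, the fixed intercept mixes with an autocorrelation time in the
thousands; with them its effective sample size is comparable to the
hazard parameters'. Defaults are 2 chains of 20,000 iterations (10,000
burn-in, thin 10); the tests and the acceptance script run reduced
budgets (documented below). Split-$\hat R$ and autocorrelation-based
effective sample sizes are reported per scalar; any $\hat R > 1.1$ flags
the posterior as non-converged, prominently.

## Dynamic prediction

For a patient decision-free at landmark $t$ with history
$\mathcal{Y}_i(t)$, the probability of a resectable decision by horizon
$u$ is

$$\pi_i(u \mid t) = 1 - \frac{S_i(u \mid b_i, \theta)}{S_i(t \mid b_i, \theta)},$$

averaged over posterior draws of $\theta$ and, for each draw, over the
conditional law of $b_i$ given the history. Because the longitudinal
model is linear-Gaussian, that conditional is exactly Gaussian, so the
package draws from the closed-form conjugate conditional rather than
running an inner Metropolis chain — the same target with zero inner
Monte-Carlo error and less computation. (Conditioning is on the history
only, not additionally on survival to $t$ through $b_i$; survival to $t$
enters through the ratio above.) The report is the Monte-Carlo mean with
2.5/97.5 percentile bands over 200 draws by default. `sequential_update()`
re-evaluates the forecast at every measurement time, and `autoplot()`
renders the two-panel display (trajectory, then probability); for
sequential objects both renderings of the right panel are available —
probability versus horizon at a fixed landmark, and the final-horizon
probability versus landmark — since either convention is found in
practice.

## Validation metrics

`cross_validate_jm()` refits the joint model on each training split of a
stratified 5-fold partition (sizes differ by at most one, outcome
proportions balanced) and scores test-fold patients still decision-free
at the landmark. Discrimination is the time-dependent AUC in Mann–Whitney
form (ties one half) and accuracy the Brier-type prediction error; both
use inverse-probability-of-censoring weights from a Kaplan–Meier
estimator of the censoring distribution among patients at risk at the
landmark. The evaluation window defaults to landmark = week 9 (end of
the third cycle — the earliest time the decision is clinically live) and
horizon = end of follow-up; there is no canonical choice of
evaluation times for this endpoint, so both are configurable. Inside cross-validation the
MCMC budget is reduced (defaults: one chain, 2,000 iterations) to keep a
full run at desk scale; the fold-level metrics are noisier but unbiased.
Fixed cut-off comparators (`cutoff_predictor_auc()`: value below a
threshold at nadir, after the third cycle, or pre-surgery) and simple
two-group tables (`two_group_tests()`: Fisher exact for categories,
Mann–Whitney for continuous variables) mirror how such cohorts are
conventionally summarized. `odds_ratio_2x2()` uses $ad/bc$ with Haldane's
0.5 correction, a Woolf log-scale interval, and a Fisher exact p-value.

## The synthetic cohort generator

`generate_cohort()` draws from exactly the model above, so recovery
studies are well-posed. The default `cohort_config()` is the package's
*stated world*, fixed once from the reference cohort profile and not
revisited: 77 patients; transformed-scale intercept 3.4155 (baseline
median 926 IU/mL) with random-intercept SD 0.9 reproducing the heavy
right tail (range roughly 20–30,000 IU/mL); per-cycle and
per-paracentesis multiplicative effects $\log 0.89$ and $\log 0.76$ on
the transformed scale; visits every 3 weeks with 2–6 samples per patient
(median 5, the per-patient count drawn from a fixed marginal — the
reference profile states only the median and range, so the dropout
mechanism, *measurement stops after the first $n_i$ scheduled visits*, is
a modelling choice mirroring marker recording up to the third or fourth
cycle); 3–9 total cycles (median 6, 40% with 3–4); 88.3% ascites, 39%
epigastric carcinomatosis, 15.6% needing paracentesis with counts
(1,2,4,6) in proportions (3,7,1,1)/77, paracentesis implying ascites;
hazard coefficients $\log 0.57$ per PS unit and $\log 0.39$ for
epigastric disease; association $\alpha = -0.35$ (higher marker, lower
chance of a resectable decision); and a piecewise baseline hazard that is
near zero before week 9 — a decision needs at least three cycles — with
rates (0.002, 0.085, 0.136, 0.187) per week on pieces split at weeks 9,
15 and 21, calibrated once so that ~52% of patients are resectable by the
27-week administrative end of follow-up. Event times are drawn by
inverting the numerically integrated cumulative hazard against an
exponential deviate with bracketed root-finding; decision times are
floored at one visit interval so every patient has at least two samples.

What the generator does *not* emulate: assay noise spikes, visit-time
jitter, informative dropout beyond the decision itself, centre effects,
or any misspecification of the trajectory shape. A green recovery test
therefore establishes internal consistency of estimator and sampler, not
robustness to model violation.

`fixture_patients()` ships the four illustrative patients (A–D) whose
printed histories span the clinically interesting contrasts. Their
decision times and within-treatment paracentesis timings are not part of
the printed record and are reconstructed by convention (decision three
weeks after the last sample; paracenteses at early visits); they are
labelled as such and never used as numeric targets — per-patient probabilities depend
on the cohort a model was fitted to, which is unavailable here, so the
tests assert only directions and orderings (a declining trajectory gains
probability as evidence accrues; a flat high trajectory ends lower).

## Numerical choices and degenerate inputs

* Quadrature segments are cut at hazard knots, covariate jumps, landmarks
  and horizons, so no segment straddles a discontinuity; probability at
  the landmark is exactly zero by construction.
* Perfect separation in the hazard fit is detected (|coefficient| > 15)
  and flagged rather than returned silently; datasets with no events are
  rejected.
* A rank-deficient longitudinal design names its collinear columns;
  zero-variance screening candidates are skipped with a warning.
* Subjects with no measurements get prior-mean random effects, flagged.
* $D = 0$ and $\sigma \to 0$ limits are handled: the GLS step and the
  empirical-Bayes formulas degrade gracefully to their closed-form
  limits.
* With fewer distinct event times than requested pieces the knot rule
  falls back to time terciles.

## Reduced budgets in the tests

The acceptance-grade checks run at deliberately reduced MCMC budgets
(single chain, 1,500–3,500 iterations) and scaled-down replicate counts
(5 recovery replicates at n = 300; the 10,000-patient calibration checks
run at 2,000). These sizes were chosen for runtime, not tuned to
outcomes; the same checks pass with larger budgets, and the defaults in
`jm_control()` remain the full-length settings.

## Known limitations

* Only the current-value association is implemented; no competing risks,
  no stratified baselines, no Hamiltonian sampler.
* The covariate-path extension beyond the last measurement is a
  convention; with real registry data the cycle calendar should be
  supplied, not imputed.
* Time-dependent AUC/PE use Kaplan–Meier censoring weights, which assume
  censoring independent of the marker conditional on nothing — adequate
  here because censoring is administrative in the generator, but a
  covariate-dependent censoring model would be needed otherwise.
* The headline values reported for the reference 77-patient cohort
  (multivariate hazard ratios 0.57/0.39, cross-validated accuracy 88%
  [82–100], prediction error 2.24% [0–2.32]) cannot be recomputed because
  that cohort is unavailable; nothing in this package asserts them
  numerically, and the acceptance suite replaces
  them with parameter-recovery and discrimination properties on the
  stated world.

## A minimal session

```{r, eval = FALSE}
library(ca125jm)

coh <- generate_cohort(cohort_config(n_patients = 77, seed = 1))
fit_lme(coh$longitudinal)
univariate_screen(coh$baseline, c("ps", "pc_epigastric", "ascites"))

fit <- fit_jm(coh$longitudinal, coh$baseline,
              control = jm_control(n_chains = 1, n_iter = 2500,
                                   burn_in = 1000, thin = 5), seed = 1)
tidy(fit)

fx <- fixture_patients()
sq <- sequential_update(fit,
                        dplyr::filter(fx$longitudinal, patient_id == "A"),
                        dplyr::filter(fx$baseline, patient_id == "A"))
autoplot(sq)

cross_validate_jm(coh$longitudinal, coh$baseline, seed = 1)
```
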