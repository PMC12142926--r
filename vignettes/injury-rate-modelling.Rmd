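---
title: "Modelling surveillance injury rates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling surveillance injury rates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the likelihood families and priors, the sampler and its diagnostics, the
posterior predictive checks, the model-comparison criterion, and — since
surveillance microdata are rarely shareable — the synthetic data
generator that stands in for them. It also records the design decisions
that were genuinely open, and what the package's passing tests do and do
not establish about real data.

## The data model

A surveillance table has one row per stratum: school, division
(DI/DII/DIII), academic year, sport, event type (practice/competition),
diagnosis (sprain/strain/contusion/concussion), the injury count, and
the athlete-exposure (AE) denominator — one athlete participating in one
practice or competition event. Two conventions matter:

* **Level sets are declared, not inferred.** Strata with zero injuries
  are real observations; inferring levels from observed data would
  silently drop empty categories that the zero-proportion check needs.
  The first declared level of each covariate is the reference.
* **Sports are analysed separately.** Injury profiles differ enough by
  sport that a pooled fit is not meaningful; `fitModel()` refuses mixed
  tables.

The raw rate is `injuries / AEs * scale`, reported per 10,000 AEs by
default (1,000 is the other common convention; pass `scale`).

## Likelihood families

Counts in stratum *i* are modelled on the count scale with the exposure
inside the mean, `mu_i = AE_i * lambda_i`, and

`log lambda_i = gamma + alpha_event + beta_division + epsilon_diagnosis
+ kappa_year (+ zeta_school)`

under reference ("corner") coding: a one-parameter-per-level
parameterization is unidentifiable, and reference coding makes every
exponentiated coefficient a rate ratio against the reference cell,
which is how such models are conventionally reported.

The four families form a ladder of flexibility:

1. `poisson` — equidispersed baseline.
2. `poisson_school` — adds `zeta_school ~ Normal(0, sigma_zeta)`.
   Between-school differences (staffing, reporting practice) are a
   dominant source of extra-Poisson variation in surveillance data, and
   a multiplicative school effect is the minimal model of them. Effects
   are drawn once per school and shared by all of that school's rows.
3. `nb_school` — NB2: variance `mu + mu^2/kappa`, overdispersion
   `kappa > 0`. Note the naming: `kappa_year` are the year effects and
   `kappa_nb` the NB overdispersion; the conventional symbol is kappa
   in both roles, so the package disambiguates in code.
4. `zinb_school` — a structural zero with probability `theta`, indexed
   by event type only (`theta[practice]`, `theta[competition]`), mixed
   with the NB count: `P(0) = theta + (1-theta) NB(0)`. Zero inflation
   acts at the row level. The school effect enters only the count mean,
   not the zero-inflation probability; one `theta` per event type is
   estimated freely.

All pmfs are exact and tested to normalize to 1; the NB reduces to the
Poisson as `kappa -> infinity` and the ZINB to the NB at `theta = 0`.

## Priors

Fixed effects and the intercept get Cauchy(0, 10): on the log-rate
scale this is extremely permissive (one scale unit is a rate ratio of
e^10), so it behaves as a weakly informative prior that only truncates
absurd tails. `sigma_zeta` gets half-Cauchy(0, 10). For the parameters
with no conventional published choice the package declares:
half-Cauchy(0, 10) on `kappa_nb` (matching the same weak-scale
convention) and Uniform(0, 1) = Beta(1, 1) on each `theta`. For the
intercept-only Poisson model the intercept prior may instead be a
Gamma(shape, rate) on the baseline rate `exp(gamma)`, which makes the
posterior available in closed form (`conjugate` module) and gives the
sampler an analytic oracle.

The Gamma–Poisson module uses the (shape, rate) parameterization so
the conjugate update is literally additive: shape gains the injuries,
rate gains the exposures. `priorSensitivity()` updates several priors
on the same data and reports the maximum pairwise relative difference
of posterior means; with ~10,000 exposures the four `demoPriors()`
(pseudo-exposure weights 1 to 600) move the posterior mean by under 2%.

## Sampling

The posterior is explored with an adaptive Hamiltonian sampler on the
unconstrained scale (`log sigma_zeta`, `log kappa_nb`,
`logit theta`, with log-Jacobians included):

* dynamic no-U-turn trajectory building (slice formulation, doubling
  until a U-turn or maximum depth 10; divergence when the energy error
  exceeds 1000);
* dual-averaging step-size adaptation toward acceptance 0.9;
* windowed diagonal mass-matrix estimation during warmup (a step-size
  buffer, doubling estimation windows, a terminal buffer), with the
  step size re-tuned after each metric update;
* the zero-inflation indicator marginalized analytically, keeping the
  parameter space continuous for gradient-based sampling.

Likelihood and gradient kernels are compiled (Rcpp); the sampler driver
is plain R. Chains are initialized uniformly in a small ball around
zero on the unconstrained scale, jittered per chain from the seed, and
the same seed plus configuration reproduces draws exactly. The default
configuration is 4 chains of 1000 warmup and 1000 sampling iterations.

The backend is a contract, not a binding: any sampler accepting a log
joint density with gradients, a seed and a chain count, and returning
tagged draws, can stand behind `fitModel()`.

**Diagnostics.** `computeRhat()` is the rank-normalized split R-hat
(maximum of the bulk and folded variants), `computeESS()` the bulk
effective sample size via Geyer's initial monotone positive-pair
truncation of the chain-combined autocorrelations. Convergence is
declared only when R-hat ≤ 1.01 *and* ESS ≥ 400 for every parameter.
Zero-variance chains are handled deterministically: R-hat 1, ESS 0,
flagged degenerate (so a constant parameter fails the gate rather than
passing it vacuously). The diagnostics are tested against closed
forms: iid chains give ESS near the draw count, an AR(1) chain with
correlation 0.9 gives ESS near N·(1−ρ)/(1+ρ), separated chains give
R-hat far above 1.01.

## Posterior predictive checks

`generateReplicates()` simulates full count datasets from evenly
thinned posterior draws with the observed AEs as offsets. Four checks
interrogate them:

1. **Maxima exceedance** — per group, the percentage of replicates
   whose maximum *strictly* exceeds the observed maximum (ties count as
   non-exceedance, which keeps the 0% boundary interpretable).
   Percentages collapsing to 0 mean the model cannot generate the
   observed extremes — the signature failure of the Poisson on
   overdispersed counts.
2. **Zero proportions** — observed percentage of zero strata per group
   against the equal-tailed 95% interval of the replicate percentages
   (quantile type 7).
3. **Actual vs predicted rates** — per-row predictive medians and 90%
   intervals, plus the OLS regression of medians on actual rates;
   calibrated predictions give slope 1, intercept 0. Error bars on the
   *actual* rates are Jeffreys Gamma intervals on the observed count —
   an explicit reporting convention of this package, since an observed
   rate carries no posterior of its own.
4. **Randomized PIT** — for discrete counts the plain PIT is
   non-uniform even under the true model, so the package draws the PIT
   uniformly between the posterior-averaged predictive CDF at `x-1`
   and at `x`. The eCDF of the PIT values is compared with a pointwise
   95% envelope simulated from true uniforms at matching sample size,
   and summarized by the Kolmogorov–Smirnov distance.

Under a correctly specified model all four checks are calibrated, which
the tests verify at reduced size; on zero-inflated overdispersed data
they reproduce the expected ranking (Poisson fails maxima, zeros and
PIT; NB and ZINB pass all three and are nearly indistinguishable).

## Model comparison

`psisLoo()` computes the expected log pointwise predictive density
under leave-one-out cross-validation from a single posterior sample,
using Pareto-smoothed importance sampling: per observation the inverse
likelihood ratios are tail-smoothed by a generalized Pareto fit
(profile-posterior method with the standard weak regularization), and
observations with tail shape above 0.7 are flagged; for small tables
`exactLooRefit()` is the refit fallback and the test oracle. Pointwise
likelihoods for hierarchical families condition on the sampled school
effects (within-sample prediction for existing schools), the default
factorization computable from draws; prediction for *new* schools would
require marginalizing `zeta` and is out of scope. `compareModels()`
ranks by ELPD and reports differences against the top model with the
standard error of the pointwise differences — the "within 2 SE" scale
on which near-ties are declared.

## The synthetic generator

Raw surveillance microdata are typically not depositable, so the
generator emulates the structure of a five-season collegiate soccer
surveillance program and is the package's test bed. Defaults (declared
once, used everywhere):

* **Structure**: 10 schools per division × 3 divisions × 5 seasons ×
  2 event types × 4 diagnoses = 1,200 strata per sport. School counts
  per division are not published for such programs; 10 is desk-scale
  and exhibits clear between-school variance.
* **Effects**: the event, division and diagnosis effects equal the
  published posterior means for the sport's NB model (e.g. women's
  soccer competition effect 1.33, concussion-vs-sprain −0.99); year
  effects, which are not published, are small declared values
  (±0.02–0.04); `sigma_school = 0.3`, `kappa = 2`, and for the ZINB
  family `theta = 0.25` per event type — plausible magnitudes for
  reporting heterogeneity, surveillance overdispersion and structural
  non-reporting, chosen once.
* **Exposures**: per-stratum AEs are log-normal (sdlog 0.5) with an
  event-type-specific location calibrated so expected AE totals match
  the published season totals (practice exposure ≈ 3× competition).
* **Baseline**: `gamma` is calibrated in closed form so expected injury
  totals sit on the published magnitudes. The published totals imply a
  competition/practice rate ratio (≈2.8–2.9) slightly below the
  published model effect (exp(1.33) ≈ 3.8); one intercept cannot match
  both event-type totals exactly, so the calibration averages the two
  implied baselines on the log scale, leaving each total matched to
  within ~15%.

The generator records a `TruthManifest` (including the realized school
effects) so `recoveryReport()` can score bias, z-scores and 95%
interval coverage of any fit against the generating values.

**What the generator does not emulate**: reporter misclassification,
athletic-trainer staffing effects beyond the school multiplier,
within-season exposure structure, or real diagnosis mixes. Passing
tests therefore establish internal validity — the pipeline recovers
the processes it assumes, at surveillance-like scale — not that any
family is adequate for a particular real program; that judgement is
exactly what the PPC suite is for on real data.

## Numerical choices and degenerate inputs

* Counts parse with thousands separators; zero AEs are rejected (the
  rate is undefined).
* `log(theta + (1-theta) NB(0))` is computed via log-sum-exp;
  `theta = 1` yields probability one at zero and `-Inf` elsewhere.
* The sampler returns `-Inf` (treated as a divergence) when the linear
  predictor exceeds 45, preventing overflow during warmup.
* Aggregation collapses covariates to the sentinel level `"(all)"` so
  aggregated tables remain valid tables; aggregation is associative.
* Ties in the rank-normalization use average ranks with the standard
  3/8 fractional offset.
* Headline rate ratios round half away from zero to one decimal
  (exp(1.33) = 3.781 → 3.8; interval (1.23, 1.44) → (3.4, 4.2));
  interval bounds are exponentiated directly, never re-estimated on
  the ratio scale.

## Frequentist comparator

`fitFrequentistNB()` fits the identical NB model by maximum likelihood
(glmmTMB, nbinom2, log-AE offset, school random intercept, Laplace
approximation — recorded in the output) with Wald 95% intervals. With
weakly informative priors and dense data the Bayesian and frequentist
point estimates coincide closely; the package asserts this on dense
synthetic data. The interpretations differ: the credible interval is a
probability statement about the parameter, the confidence interval a
repeated-sampling statement about the procedure.

## Problem sizes used by the test suite

The suite exercises full-scale behaviour once (the 1,200-stratum NB
fit at 4 × 1000/1000, which must pass the convergence gate) and runs
the calibration studies at reduced size as a deliberate choice of
desk-scale defaults: the 10-seed recovery study and the LOO ordering
study use 2 chains × 300/300 on 1,200 strata; the PPC ranking study
uses 360 strata; the exact-LOO oracle uses 20 single-school strata.
The reduced-draw recovery study requires each fixed effect's 95%
interval to cover truth in at least 8 of 10 replicates
(binomial(10, 0.95) lower tail); the long-form version of the same
experiment is 20 seeds with a 17/20 threshold.

## Known limitations

* Fixed-metric HMC handles the heavy Cauchy prior tails poorly far
  from the data-supported region; with any realistic amount of data
  the posterior is well-behaved and this does not bite, but
  prior-only sampling of Cauchy(0, 10) is not supported.
* The LOO factorization conditions on school effects; ELPD is not
  comparable across packages that marginalize new-group effects.
* Year is categorical; no smooth secular-trend model is provided.
* Continuous covariates, interactions and non-log links are out of
  scope: surveillance covariates of interest here are categorical and
  multiplicative on the rate.
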