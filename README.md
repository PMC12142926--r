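# injurybayes

Bayesian hierarchical count models for sport injury surveillance rates.

## The problem

Injury surveillance systems (for example, collegiate programs in which
athletic trainers report injuries and participation for their teams)
summarize risk as an *injury rate*: injuries divided by *athlete
exposures* (AEs, one athlete taking part in one practice or competition),
conventionally standardized per 1,000 or 10,000 AEs. The traditional
estimate is the raw ratio. `injurybayes` instead treats the stratified
injury counts as outcomes of an explicit data-generating process, which
yields full posterior uncertainty for every stratum, stable estimates in
sparse strata, and principled tools for deciding whether the assumed
process is adequate.

The package is aimed at injury epidemiologists and sports-medicine
biostatisticians working with tables of the form
*(school, division, academic year, sport, event type, diagnosis,
injuries, athlete exposures)*.

## The models

For stratum *i* with count X<sub>i</sub> and exposures AE<sub>i</sub>,
four nested families are available:

1. **Poisson**: X<sub>i</sub> ~ Poisson(λ<sub>i</sub> · AE<sub>i</sub>)
2. **Poisson + school effects**: adds a school random intercept
   ζ<sub>school[i]</sub> ~ Normal(0, σ<sub>ζ</sub>)
3. **Negative binomial (NB2) + school effects**: variance
   μ + μ²/κ with overdispersion κ > 0
4. **Zero-inflated NB + school effects**: a structural zero with
   probability θ<sub>event[i]</sub> mixed with the NB count

with the shared log-linear rate model

    log λ_i = γ + α_event[i] + β_division[i] + ε_diagnosis[i] + κ_year[i] (+ ζ_school[i])

under reference coding (practice, Division I, sprain and the earliest
season absorbed by the intercept), so each exponentiated coefficient is
a rate ratio against its reference level. Priors are weakly
informative: Cauchy(0, 10) on the intercept and fixed effects,
half-Cauchy(0, 10) on σ<sub>ζ</sub> and κ, Uniform(0, 1) on each θ.

Models are fitted by an adaptive Hamiltonian sampler (dynamic
no-U-turn trajectories, dual-averaging step size, diagonal mass
adaptation; likelihood gradients in compiled code), and every fit is
gated on rank-normalized split R-hat ≤ 1.01 and bulk ESS ≥ 400 for all
parameters. Model adequacy is probed with a four-part posterior
predictive check suite (maxima exceedance, zero proportions,
actual-vs-predicted rates, randomized PIT) and families are compared
with PSIS-LOO cross-validation. A synthetic surveillance-data generator
with a recorded ground-truth manifest supports calibration and
parameter-recovery studies, and a conjugate Gamma–Poisson module covers
the single-rate case in closed form.

## Worked example

The single-rate case first: with a flat Gamma(1, 1) prior and 84
injuries observed across 10,000 AEs, the conjugate posterior for the
rate is Gamma(85, 10001):

```r
library(injurybayes)
post <- gammaPoissonPosterior(gammaPrior(1, 1), injuries = 84, exposures = 10000)
round(ratePosteriorSummary(post, scale = 10000), 1)
#>   mean median  lower  upper
#>   85.0   84.7   67.9  104.0
```

so the posterior mean rate is 85.0 per 10,000 AEs with 95% credible
interval 67.9–104.0 — the data dominate the prior (compare the raw rate
84). `priorSensitivity(demoPriors(), 84, 10000)` shows the posterior
means move by under 2% across four priors of very different shape.

A full hierarchical fit on a desk-scale synthetic dataset (4 schools
per division, 3 seasons, 288 strata):

```r
sim <- generateDataset(defaultTruth("womens_soccer"),
                       defaultStructure("womens_soccer",
                                        schoolsPerDivision = c(DI = 4L, DII = 4L, DIII = 4L),
                                        years = c("2014/15", "2015/16", "2016/17")),
                       seed = 1)
fit <- fitModel(sim$table,
                modelSpec("nb_school", levelSets = defaultLevelSets(
                  years = c("2014/15", "2015/16", "2016/17"))),
                mcmcConfig(chains = 4, warmupIterations = 600,
                           samplingIterations = 600, seed = 1))
checkConvergence(fit)
#> ConvergenceReport over 23 parameters
#>   max R-hat 1.0068 (threshold 1.01): PASS
#>   min ESS 564 (threshold 400): PASS

s <- summarizePosterior(fit, includeSchools = FALSE)
rateRatioTable(s)[1:2, c("label", "mean", "lower", "upper",
                         "rate_ratio", "ratio_lower", "ratio_upper")]
#>                        label   mean lower upper rate_ratio ratio_lower ratio_upper
#> 1 Competition (vs. Practice)  1.370  1.19  1.55        3.9         3.3         4.7
#> 2               DII (vs. DI) -0.093 -0.58  0.43        0.9         0.6         1.5
```

Read the first row as: the injury rate in competition is about 3.9
times the practice rate (95% CrI 3.3–4.7) — close to the generating
competition effect of 1.33 on the log scale (exp(1.33) ≈ 3.8). The
full pipeline (fit all four families, convergence gates, PPC figures,
LOO comparison, frequentist NB comparator) runs from a single config
file via `runWorkflow()`; see `inst/scripts/run_workflow.R`.

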