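---
title: "Latent models of white matter microstructure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent models of white matter microstructure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmlatent)
```

## The scientific problem

MRI yields several per-tract scalar summaries of white matter
microstructure: fractional anisotropy (FA, directional coherence of water
diffusion), intra-neurite volume fraction (INVF, a neurite-density
compartment estimate), and the magnetization transfer ratio (MTR, sensitive
to myelin content). Whether such markers generalize across tracts — i.e.
whether a *general factor* of white matter integrity, neurite density or
myelination exists — determines how individual differences in brain
structure can be related to cognitive outcomes such as fluid intelligence
without drowning in tract-wise multiple comparisons and measurement error.

`wmlatent` implements a complete latent-variable workflow for this
question: 52 atlas tracts averaged into 10 functional cluster indicators (5
bilateral systems × 2 hemispheres), a family of twelve competing
confirmatory factor architectures per marker, full-information maximum
likelihood (FIML) estimation that accommodates planned missingness (one
marker acquired at a single site; MRI available for a subset), AIC/Akaike
weight model comparison, joint three-marker models, a latent regression of
fluid intelligence on the marker general factors, an age-controlled
replication, and noncentral-χ² power analysis for a target RMSEA.

## Model specification

A model is a parameter table over loadings (`=~`), regressions (`~`),
(co)variances (`~~`) and intercepts (`~1`); free parameters carry labels,
and shared labels are equality constraints. Implied moments follow the
standard structural algebra: collecting all directed paths in `A`,
exogenous (co)variances in `S` and selecting observed rows with `F`,

$$\Sigma(\theta) = F\,(I-A)^{-1} S\,(I-A)^{-\top} F^{\top},
  \qquad \mu(\theta) = F\,(I-A)^{-1} m .$$

Identification conventions, applied uniformly:

* every latent (residual) variance is fixed to 1 and all loadings are free;
* a latent measured by exactly two variables gets equality-constrained
  loadings (local identifiability), which also covers a general factor
  measured by two sub-factors in the hierarchical architectures;
* bifactor group factors (hemispheres; association/projection; method
  factors) are orthogonal to the general factor and to each other, written
  as explicit `fixed(0)` covariances;
* reflection invariance is resolved in reporting (standardized solutions),
  not by constraining signs during optimization.

The twelve architectures (`wm_model_names()`) cross three design axes:
whether indicators are modeled directly or through bilateral cluster
latents capturing left/right shared variance; whether a general factor is
present, absent, or mediated by an association/projection layer; and
whether orthogonal secondary factors absorb association/projection or
hemisphere-specific variance. `"BiClusHem-BiF"` (general factor over five
bilateral cluster latents plus orthogonal left/right hemisphere bifactors)
and `"HiBiClusHem-BiF"` (the same with an intermediate association-fibers
latent) name the two hemisphere-bifactor bilateral variants.

### Covariates: identification policy

The data-source dummy (site A = 0, B = 1) and residualized age enter as
observed exogenous variables with free mean and variance. We regress them
on the *cluster-level common factors* (the bilateral cluster latents, or
the general/association/projection factors where those load directly on
indicators, and the fluid-intelligence factor) — deliberately **not** on
every latent, for two reasons established while building the engine:

1. an upstream factor that loads only on other latents (e.g. the general
   factor above bilateral cluster latents) transmits its covariate effect
   to the indicators exclusively through the downstream latents' own
   regressions; a separate upstream slope is then perfectly collinear with
   them, and the information matrix is singular by construction;
2. an orthogonal bifactor with residual variance fixed to 1 can trade a
   growing covariate slope against shrinking loadings almost flatly — the
   factor degenerates into a proxy for the covariate. Under strong age
   effects this ridge manifests as diverging slope estimates and spurious
   "singular convergence".

The restricted regression set spans the identified part of the covariate
effect on the indicator moments. As insurance against remaining
weakly-identified ridges, regression slopes are box-bounded at ±30 during
optimization — far outside any plausible estimate on standardized data.
One consequence is that degrees of freedom differ slightly from analyses
that formally attach a (redundant) slope to every latent: the
hemisphere-bifactor bilateral model has df = 30 with the source dummy here.

For a marker acquired at a single site (MTR), no latent carries information
about the site contrast, so such markers are excluded from the dummy's
targets in joint models; their measurement-model comparison runs within the
acquiring site without the dummy.

## Estimation

The casewise (full-information) log-likelihood sums, over rows, the normal
log-density of each row's observed subset under the subset-marginalized
implied moments. Rows are grouped by missingness pattern with per-pattern
sufficient statistics, so one evaluation costs O(#patterns · p³) regardless
of n. Analytic gradients are propagated from the per-pattern moment
gradients through the structural matrices (verified against central finite
differences to ~1e-6 in the test suite).

* **Optimizer**: quasi-Newton (`nlminb`, PORT) with the analytic gradient;
  start values are loadings 0.5, regressions 0, intercepts at column means,
  observed variances at (half) the sample variance; `restarts` additional
  runs from uniformly jittered starts guard against multimodality of
  bifactor likelihoods, keeping the best converged solution.
* **Variance parameters** are optimized on the log scale by default; the
  `"raw"` mode leaves them unbounded so that negative variance estimates
  (Heywood cases) are observable — required by the negative-variance rule,
  and used by the pipeline stages.
* **Saturated model**: closed-form ML on complete data; under missingness,
  the standard EM algorithm for the unstructured multivariate normal,
  iterated to a 1e-10 relative log-likelihood tolerance. The test statistic
  is χ² = 2(ℓ_sat − ℓ_model), a definition that stays valid under planned
  missingness and reproduces the usual statistic on complete data (tested).
* **Standard errors** come from the inverse numerical Hessian of the
  negative log-likelihood at the optimum (finite differences of the
  analytic gradient), delta-transformed to the natural scale for
  log-parameterized variances.

### The negative-variance rule and admissibility

After a raw-scale fit, any free variance estimated negative with a
non-significant raw-scale Wald test (p ≥ .05) is fixed to 0 and the model
refitted, iterating to a fixpoint; a *significant* negative variance is
left free and flagged as a genuine Heywood case. A solution is inadmissible
— excluded from model comparison, but always reported with its verdict — if
the optimizer did not converge, the parameter variance–covariance matrix is
not positive definite, or the implied latent covariance matrix is not
positive definite (tolerance: eigenvalues below −1e-8 relative to the
largest magnitude).

## Fit assessment, comparison and power

CFI, TLI, RMSEA (with n − 1) and SRMR follow the conventional definitions;
the baseline is the independence model (free means and variances, zero
covariances) estimated with the same FIML machinery on the same
missingness, and SRMR compares the model-implied covariance against the
saturated FIML estimate. Conventional cutoffs (≥ .90 / ≤ .08 acceptable,
≥ .95 / ≤ .05 good) are reported but model *selection* uses AIC = −2ℓ + 2q
transformed to Akaike weights with the min-AIC shift; winners within 0.005
of the top weight are reported jointly (ties occur naturally when a
hierarchical variant collapses onto its parent). TLI is reported unclipped.

Power for detecting misfit is the probability that the exact-fit
likelihood-ratio test rejects when the population RMSEA is ε: the critical
value is the upper-α central χ²(df) quantile and the alternative is
noncentral χ² with λ = (n−1)·df·ε². With the study's inputs (df = 27 at
N = 365; df = 26 at N = 150; α = .05, ε = .05) this yields 0.82 and 0.34.

## The synthetic cohort generator

Because the original cohort data are not redistributable, every stage is
exercised on a two-site synthetic cohort whose *defaults encode the study
design*: site A, N = 150, ages 20–74 (uniform), FA + INVF + MTR, a 48-item
5-option matrix test; site B, N = 215, ages 18–40, MRI for 200, FA + INVF
only, a 36-item 8-option untimed test.

True-model defaults (`wm_true_params()`):

* standardized loadings 0.6 (general → bilateral cluster), 0.7 (cluster →
  indicator), 0.4 (hemisphere), residuals completing unit variances —
  mid-range values chosen once as representative of well-behaved
  neuroimaging measurement models;
* cross-marker general-factor correlations .03 (FA–INVF), −.11 (FA–MTR),
  .46 (INVF–MTR) and structural coefficients of fluid intelligence 0.26
  (FA), −0.05 (INVF), 0.25 (MTR) — the published point estimates, so that
  recovery of these values is a meaningful end-to-end check;
* linear age effects of −0.02 SD/yr on marker factors and −0.015 SD/yr on
  fluid intelligence around age 45, reproducing qualitative age
  confounding (the published slopes are not printed, so these are chosen
  values, not reproductions);
* additive site shift of 0.3 SD on indicators, exercising the source dummy
  and the two-sample standardization;
* tract values = cluster indicator + N(0, 0.3²) noise, mapped onto
  plausible raw scales (FA ≈ 0.45 ± 0.08, INVF ≈ 0.55 ± 0.08,
  MTR ≈ 35 ± 3%); raw scales are placeholders — they are standardized away
  and the study's tract-level means are not printed;
* 0.5% of tract cells replaced by ±4 SD extremes to exercise the outlier
  screen; item responses follow a two-parameter logistic model with
  guessing floor 1/#options.

What the generator does *not* emulate: non-normal marker distributions,
site differences in covariance structure (only mean shifts), spatially
correlated tract noise within clusters beyond the cluster factor, item
position/speededness effects, and non-linear age trajectories. Passing
recovery tests therefore demonstrates the correctness of the pipeline under
the model's assumptions, not robustness of the scientific conclusions to
their violation.

## Preprocessing contracts

The stage order is fixed and tested: cellwise ±3 site-SD outlier removal on
raw tract values (site statistics computed once — a single discard pass),
tract-to-cluster averaging (mean of non-missing members), within-site
z-standardization, merging, combined z-standardization. Intelligence halves
(odd/even proportion correct, 1-based item order, missing responses scored
incorrect, subjects at or below chance 1/#options excluded) are
standardized the same way. Age is residualized on the site contrast by OLS
and then scaled to unit variance for numerical conditioning; slopes are
therefore per SD of residualized age.

## Numerical choices and degenerate inputs

Non-positive-definite implied covariances during optimization return a
large penalty (the optimizer backtracks); zero-SD columns abort
standardization with the column named; constant columns yield flagged
undefined partial correlations; a constant age column degrades the
age-controlled stage to the age-free analysis with a warning; all-missing
rows are rejected. Monte-Carlo problem sizes in the tests (n = 2000/site
for recovery, five replicate seeds for selection consistency, n ≈ 10⁴ for
distributional checks) were chosen so Monte-Carlo error sits comfortably
inside the asserted tolerances.

## Known limitations

* The engine covers the model family needed here (single-group, normal
  FIML, equality constraints, covariates); it is not a general SEM package
  — no multi-group models, robust corrections, or categorical indicators.
* Confidence intervals for standardized coefficients rescale the raw Wald
  interval by the implied standard-deviation ratio, ignoring the sampling
  variability of that ratio.
* Under extreme age effects (≳ 0.7 SD per age-SD on every latent) the
  fixed-unit-residual scaling still admits near-flat likelihood ridges in
  the age-controlled joint model; the slope bounds contain the estimates
  but the fit may be declared non-converged. The study-calibrated defaults
  sit far from this regime.
* The hierarchical (higher-order) joint structure is usually inadmissible
  on cohorts generated without a common higher-order factor — the expected
  outcome, mirroring its rejection on the real data — so downstream stages
  default to the correlated-factors structure when the comparison rejects
  the alternative.
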