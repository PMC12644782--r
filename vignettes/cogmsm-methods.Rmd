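---
title: "Modelling cognitive ageing with panel-observed multistate models"
author: "cogmsm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive ageing with panel-observed multistate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmsm)
```

## The model

`cogmsm` implements a continuous-time Markov model for cognitive ageing
observed as panel data. The state space is normal cognition (NC), mild
cognitive impairment (MCI), dementia (DEM) and death, with death absorbing.
A direct NC → DEM transition is not allowed: subjects observed to jump from
normal cognition to dementia between two visits are assumed to have passed
through an unobserved MCI phase, which the interval-censored likelihood
integrates out. MCI ⇄ NC is the only reversible pair, reflecting the
well-documented instability of mild cognitive deficits in community
settings.

Age is the time scale. Each allowed transition $r \to s$ has a Gompertz
baseline intensity with proportional covariate effects,

$$q_{rs}(a, x) = \exp\{\lambda^*_{rs} + \gamma_{rs}(a - a_{\mathrm{ref}})
  + \beta_{rs}^\top x\},$$

where $\lambda^*_{rs}$ is the log hazard at the reference age
$a_{\mathrm{ref}}$ (default 60 years, a typical youngest entry age;
centring the age term keeps the optimisation well scaled), $\gamma_{rs}$
is the Gompertz slope in 1/year, and $\exp(\beta)$ is the per-transition
hazard ratio that the analysis reports. Covariate effects are estimated
freely per transition; by default they are placed on the three cognitive
transitions (NC→MCI, MCI→NC, MCI→DEM), the ones for which hazard ratios
are of scientific interest, and can be extended to the death transitions
via `beta_transitions`.

## Observation scheme and likelihood

Subjects are seen at scheduled visits (every 6 years below age 78, every
3 years after), so transition times are interval-censored. The likelihood
of one subject is computed by a forward pass over state distributions:

* a known state conditions the distribution on that state;
* a visit at which the subject is known to be alive and dementia-free but
  of unknown stage restricts the distribution to the censored set
  {NC, MCI} — the restriction propagates *jointly* into later intervals
  rather than being summed per interval, which matters whenever two or
  more censored visits are adjacent;
* an exact death age $t$ (from a death registry) contributes a density,
  $\sum_s P(t_0, t)[\cdot, s]\, q_{s,\mathrm{DEATH}}(t)$. Because dementia
  status at death is ascertained for everyone (registry and chart review),
  the death observations partition into dementia-free deaths (the sum runs
  over $s \in \{NC, MCI\}$) and deaths with dementia, for which the
  pre-death state is DEM and dementia onset is thereby located in the
  interval since the last assessment.

A subject with a single observation contributes zero and is retained for
bookkeeping. Record weights multiply log-likelihood contributions, which
is what the attrition-weighting module relies on.

Transition probability matrices over an interval solve the Kolmogorov
forward equations for the age-dependent generator. The default is a
piecewise-constant approximation — a product of matrix exponentials of
$Q(\text{midpoint})\,\Delta$ over a grid of width at most `step` (default
1 year) — with two refinements: the grid always splits at the age
threshold when covariate effects are age-dependent, and a single factor is
used when all slopes are zero, where the approximation is exact. An
adaptive ODE solution (`method = "ode"`, via deSolve) serves as an
internal oracle; the test suite checks that the piecewise solution
converges to it as the step shrinks (relative error below $10^{-4}$ at a
0.05-year step on a Gompertz fixture).

## Estimation

`fit_msm()` maximises the panel likelihood over the unconstrained vector
(log rates, slopes, betas) with BFGS, using finite-difference gradients
computed in compiled code, and takes the covariance matrix as the inverse
observed negative Hessian. Starting values are crude occurrence/exposure
rates with zero slopes and betas; in our simulations this initialiser is
good enough that a single start converges reliably, so multi-start is
available (`control$n_start`, jittered starts with fixed seeds) but off by
default to keep repeated simulation fits affordable. Convergence requires
both optimizer success and a small score norm; a singular Hessian marks
the covariance (and hence confidence intervals) unavailable rather than
failing the fit. Confidence intervals are Wald intervals on the log
scale, matching the hazard-ratio reporting convention; profile likelihood
is not attempted.

Subjects with extreme proposals during optimisation are protected by
clamping each log intensity at 5 (about 150 events/year), far above any
plausible optimum; invalid proposals yield a large penalty instead of an
error.

## Biomarker coding

Serum biomarkers (Aβ42/40 ratio; p-tau181, p-tau217, t-tau, NfL, GFAP in
pg/mL) are prepared by: single-value imputation of below-LOD measurements
to 0 (a not-missing-at-random choice mirroring assay behaviour);
z-scoring against the analysis sample; and either a restricted cubic
spline or dichotomisation. The spline uses three knots at the 25th/50th/
75th percentiles of the z-scores and the Harrell restricted
truncated-power basis, normalised by the squared boundary-knot span; it is
linear outside the boundary knots, and the hazard-ratio curve uses the
median as reference, so HR(median) = 1 with a zero-width delta-method
interval. Dichotomisation uses predefined cut-offs (0.057 for Aβ42/40,
low at risk; 1.512, 0.134, 0.832, 20.171 and 142.515 pg/mL for p-tau181,
p-tau217, t-tau, NfL and GFAP, high at risk). Ties at a cut-off are *not*
at risk: the printed three-decimal thresholds make ties measure-zero, and
a strict inequality keeps `dichotomize()` consistent with
`validate_cutoff()`. Counting elevated markers uses p-tau217, NfL and
GFAP.

Cut-off re-derivation follows the published procedure: an 80/20
train/test split, then 5000 nonparametric bootstrap resamples of the
training set, each maximising Youden's J over thresholds placed at
midpoints of consecutive sorted unique values (ties broken toward higher
sensitivity, then the smaller threshold). The procedure's final cut-off
is the median of the bootstrap optima — the aggregation step is not
specified in the source description, and the median is robust to the
occasional wild resample; the mean is available by option. The 10-year
dementia outcome treats subjects dying dementia-free within the window as
non-cases and excludes subjects with insufficient dementia-free follow-up.

## Cognitive staging

The staging module turns raw test scores (five domains, seven tests) into
states: test z-scores against age-stratum baseline norms, averaged within
domains; MCI requires a domain z ≤ −1.5 (inclusive), at most one impaired
IADL, preserved basic ADLs, and no dementia diagnosis. CIND drops the
functional criteria, so CIND ⊇ MCI by construction. Subjects meeting the
cognitive but failing the functional criterion are classified NC — the
state space partitions into exactly NC/MCI/DEM — and flagged
(`functional_fail`) for transparency. Norms are frozen at baseline:
follow-up visits are scored against baseline means and SDs. Visits with
no scoreable domain are treated as the censored {NC, MCI} set. The age
strata for norms are not prescribed; the generator uses decadal strata
and the module accepts any stratification.

## The synthetic cohort generator

Because the motivating cohort data cannot be redistributed, every
downstream module is exercised against synthetic cohorts with known
ground truth. The generator emulates, at the distributional level: entry
ages 60+ as a young/old mixture with overall median near 72; 61.5%
women, 35.4% university education; comorbidity prevalences with odds
tilted by age; log-normal biomarkers whose age-72 medians, age slopes and
residual SDs are calibrated to the reference cohort's overall and
stratum-specific medians and IQRs, with a positive exchangeable residual
correlation (0.3) among the five injury markers and a negative
correlation (−0.2) with the Aβ42/40 ratio; a 17.7% baseline MCI
probability; the 6-year/3-year visit schedule with a 16-year horizon; a
configurable fraction of stage-censored visits; and optional dropout
(random per-visit, or logistic in baseline age). Trajectories are drawn
exactly from the time-inhomogeneous intensities by thinning within unit
age slices — each intensity is convex in age, so the slice maximum of the
total exit rate is attained at an endpoint and provides a valid
dominating rate for either sign of the Gompertz slope; constant-intensity
models shortcut to direct exponential sampling. Death ages tied to a
visit age are nudged by $10^{-6}$ years to preserve strictly increasing
observation times. Visit-age jitter is available but off by default so
schedule tests are exact.

What the generator does *not* emulate: the joint covariate structure of
the real cohort beyond these margins, assay noise, or time-varying
biomarkers (the design measures biomarkers at baseline only). Passing
tests therefore demonstrate the *statistical machinery* — that the
estimator recovers known intensities and hazard ratios from data with the
study's observation scheme — not agreement with the published estimates,
which are not reproducible without the restricted data.

## Attrition weighting

Dropout after baseline is modelled by logistic regression of retention on
baseline age, sex, education, chronic disease count and the six z-scored
biomarkers. Retained subjects are weighted by inverse fitted retention
probability, stabilised by the marginal retention rate and truncated at
the 1st/99th percentiles by default (both switchable — standard IPW
practice; the source description does not fix these choices), and the
model is refitted with weighted likelihood contributions.

One subtlety is worth recording. Dropout that depends only on baseline
variables conditioned on by the model (entry age is the time origin, the
first observed state anchors the likelihood) is ignorable for maximum
likelihood, so it cannot bias a correctly specified fit. The scenario in
which baseline IPW genuinely helps — and the one our simulation check
implements — is effect heterogeneity: the true biomarker effect differs
below and above age 78 while the analysis fits a single coefficient.
Age-selective dropout then shifts the exposure mix across the threshold
and with it the single-coefficient estimand; reweighting restores the
full-cohort mix. The check uses a paired design: logistic-in-age dropout
is applied to the same realised cohort that provides the dropout-free
reference fit, so the comparison isolates the selection effect, and the
dropout model is then correctly specified for the weights. Retention
probabilities stay bounded away from zero over the observed age range —
the positivity condition that inverse-probability weighting presupposes;
with near-deterministic dropout of the oldest, no reweighting of the few
retained can restore them, and the generator's `mar_age` mechanism
accepts a cap on the dropout probability for exactly that reason. That
simulation uses constant baseline intensities so that sixty replicate
fits stay affordable.

## Numerical choices and problem sizes

* Piecewise-constant step: 1 year by default (midpoint evaluation); the
  ODE oracle bounds the approximation error in tests.
* Optimiser: BFGS, relative tolerance $10^{-10}$, up to 500 iterations;
  forward-difference gradients during search, central differences for the
  final score check and the Hessian.
* Simulation scales: the recovery check uses 10 cohorts of n = 1000 with
  a true hazard ratio of 2 per NfL z-unit on MCI→DEM (pooled mean within
  [1.85, 2.15], interval coverage ≥ 80%); the simulator/likelihood
  cross-check uses 10,000 trajectories; the attrition check uses 20
  paired replicates of n = 2400 with constant intensities. These sizes
  give Monte-Carlo error comfortably inside the asserted bands while
  keeping the default suite quick.
* Degenerate inputs: single-observation subjects contribute zero and are
  kept; zero-probability sequences return −∞ and the optimiser treats
  them as a penalty; constant biomarker vectors refuse to z-score.

## Known limitations

* No frailty or random effects; no hidden-Markov misclassification layer
  (states are taken at face value once staged); no Bayesian estimation.
* Biomarkers enter at baseline only, matching the design it emulates.
* AD-subtype dementia outcomes are not modelled as competing absorbing
  states; the pipeline's scope is the all-cause dementia state.
* The equivalence of the piecewise-constant grid with any particular
  software's internal handling of the age time scale cannot be checked
  against the original estimates without the restricted cohort data.

## A worked example

```{r example, eval = FALSE}
beta <- matrix(0, 6, 1, dimnames = list(NULL, "nfl_z"))
beta[3, 1] <- log(2)  # true HR 2 per NfL z-unit on MCI -> DEM
cfg <- cohort_config(n = 1000, seed = 1,
                     true_params = default_true_params(beta = beta))
coh <- generate_cohort(cfg)
fit <- fit_msm(coh$panel, covariates = "nfl_z",
               beta_transitions = "MCI->DEM")
hazard_ratio(fit, "MCI->DEM", "nfl_z")
```
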