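---
title: "Separating within- and across-trial treatment-covariate interactions in IPD survival meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating within- and across-trial treatment-covariate interactions in IPD survival meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stratified medicine asks whether a patient-level covariate $x$ (age, sex, a
biomarker) modifies the effect of a treatment $z$ on a time-to-event
outcome.  A single trial is rarely powered for interactions, so analysts
pool individual participant data (IPD) from $j = 1, \dots, J$ randomised
trials.  A one-stage Cox model fitted to the pooled data with a naive
$x_{ij} z_{ij}$ product term estimates an *amalgamated* interaction: a
precision-weighted blend of

* the **within-trial** interaction — how the treatment effect differs
  between patients of the same trial who differ in $x$; and
* the **across-trial** association — how trial-level mean covariates
  $\bar x_j$ relate to trial-level treatment effects.

The across-trial component is an aggregate (ecological) comparison.  It is
confounded by anything else that varies between trials — the canonical
example is drug dose: if trials enrolling older patients also used higher
doses, the across-trial association attributes the dose benefit to age.
Only the within-trial component carries the patient-level causal contrast
that stratified treatment decisions need.

## The four models

All models stratify the baseline hazard by trial (a separate, unspecified
$\lambda_{0j}(t)$ per trial, so no proportionality is assumed *between*
trials) and assume proportional hazards for treatment within trial.

**Model 1** (amalgamated, fixed treatment effect):
$$\lambda_{ij}(t) = \lambda_{0j}(t)\exp\{\beta_1 z_{ij} + \beta_2 x_{ij} +
  \beta_T x_{ij} z_{ij}\}$$

**Model 2** adds a trial-level normal random effect on the treatment
coefficient, $\beta_{1j} = \beta_1 + b_{1j}$, $b_{1j} \sim N(0, \tau^2)$,
absorbing residual between-trial heterogeneity in the treatment effect.

**Model 3** (separated, fixed): centre the covariate about its within-trial
mean and add the trial mean as a trial-level moderator of the treatment
effect:
$$\lambda_{ij}(t) = \lambda_{0j}(t)\exp\{\beta_{1j} z_{ij} + \beta_2 x_{ij}
  + \beta_W (x_{ij} - \bar x_j) z_{ij}\}, \qquad
  \beta_{1j} = \alpha + \beta_A \bar x_j$$

**Model 4** is model 3 plus the random treatment effect
$\beta_{1j} = \alpha + \beta_A \bar x_j + b_{1j}$.

$\beta_W$ uses only within-trial contrasts; $\beta_A$ uses only trial-level
contrasts; $\beta_T$ mixes them.  After centring, the two columns are
orthogonal within trials, so $\hat\beta_W$ and $\hat\beta_A$ are close to
uncorrelated and the difference $\hat\beta_W - \hat\beta_A$ estimates the
magnitude of ecological bias (`ecological_bias()` takes its standard error
from the full covariance matrix rather than assuming the correlation away).
The across-trial term can also be omitted (`include_across_term = FALSE`);
$\beta_W$ keeps its interpretation.

The covariate main effect is common across trials by default
(`adjustment = "common"`), which matches how the bundled simulator
generates data and avoids the non-convergence that per-trial adjustment
terms often cause in small trials; `"per_trial"` is available.

### Centring uses the empirical mean

`centre_covariate()` centres at the *observed* within-trial mean, the only
quantity an analyst possesses.  In simulations the latent mean parameter
that generated each trial is stored separately in the truth record for
diagnostics; it is never substituted into the analysis path.

## Estimation

**Fixed-effect models** (1, 3) are ordinary stratified Cox fits, delegated
to `survival::coxph()` with Efron tie handling.  The test suite pins the
result to an independent brute-force maximisation of a hand-coded
stratified partial likelihood (agreement to $10^{-4}$).

**Random-effects models** (2, 4) maximise the *integrated* stratified
partial likelihood.  Because the random effect enters only the treatment
coefficient and trials are independent strata, the marginal likelihood
factorises over trials into one-dimensional integrals:
$$\ell(\theta, \tau) = \sum_j \log \int
  \mathrm{PL}_j(\theta, b)\,\phi(b; 0, \tau^2)\,db.$$
Each integral is evaluated by *adaptive* Gauss-Hermite quadrature: a damped
Newton search (using analytic first and second derivatives of the log
partial likelihood in $b$, computed in compiled code) locates the
conditional mode, the grid is scaled by the conditional curvature, and 15
nodes are applied (`quad_nodes`).  Doubling the node count is exposed as a
convergence diagnostic and changes the fit by less than $10^{-4}$
relatively in the tests.  The outer maximisation over the fixed
coefficients and $\log\tau$ uses `nlminb`, warm-started at the
corresponding fixed-effect fit.  $\log\tau$ is deliberately unconstrained:
box constraints made the PORT algorithm crawl along the flat likelihood
shelf that appears when $\tau \to 0$; instead the objective floors $\tau$
at $10^{-10}$ for arithmetic safety, and estimates with
$\hat\tau < 10^{-5}$ are flagged as boundary solutions (there the model has
degenerated to the fixed-effect fit, which the tests confirm to
$10^{-2}$).

Standard errors come from the inverse numerical Hessian of the integrated
log-likelihood ($\hat\tau$'s by the delta method from $\log\tau$; reported
as `NA` when the $\tau$ direction is numerically flat).  Intervals and
p-values are Wald on the log-hazard scale throughout — nothing fancier is
attempted because coverage assessment in the simulation bench is also
Wald-based.  A coefficient passing $\pm 15$ is treated as a monotone
(infinite-estimate) likelihood and reported via `converged = FALSE`, never
silently clipped.

An equivalent estimation route re-expresses the stratified Cox model as
Poisson regression on follow-up split at each trial's distinct event times
(log link, log interval-length offset, one baseline parameter per
trial-by-interval cell).  For fixed effects this reproduces the Breslow
partial likelihood *exactly*, which the test suite verifies to $10^{-6}$;
the mixed-model version (fitted by glmmTMB's Laplace approximation in a
cross-check test) integrates the full rather than the profile likelihood,
so agreement is approximate and is asserted only within half a standard
error on a small fixture.  The sharp validation of `fit_random()` is a
pure-R reimplementation of the same integrated partial likelihood using
`stats::integrate()` and `optim()`, which matches to $5 \times 10^{-3}$.

**Two-stage comparator.**  `two_stage_interaction()` fits each trial
separately and pools the interaction coefficients by inverse variance
(common-effect, or DerSimonian-Laird moments for the random-effects
variant, via `metafor::rma`).  Pooling only within-trial estimates is
automatically free of ecological bias, and on well-behaved data it tracks
the one-stage $\hat\beta_W$ to a fraction of a standard error — a useful
agreement check in applied work.  Trials with no covariate variation or a
monotone likelihood are excluded with a warning and counted.

### A note on near-invariance

Orthogonality of the centred columns does *not* make $\hat\beta_W$ exactly
invariant to dropping the across-trial term: the Cox likelihood is
nonlinear, so the decoupling is only asymptotic.  On no-confounding
fixtures ($J = 6$, $n \approx 120$) the observed shift is below a tenth of
a standard error, which is what the tests assert; under strong trial-level
confounding, dropping the term is a genuine model change and the shift can
be larger.

## The simulator

`generate_dataset()` emulates a multi-trial randomised IPD survival
meta-analysis:

1. $J$ trial sizes drawn from $N(\!N, (N/5)^2)$, rounded, floored at 10
   (the floor avoids degenerate two-patient trials; its effect is nil at
   realistic $N$).
2. Treatment $z_{ij} \sim \text{Bernoulli}(0.5)$ — individually randomised,
   1:1, no blocking.
3. Covariates.  Binary: a trial mean is drawn from
   $U(0.5 - V_1, 0.5 + V_1)$ and patients are Bernoulli with that mean.
   Continuous (age-like): a trial mean from $U(50 - V_1, 50 + V_1)$ and
   patients $N(\text{mean}, V_2^2)$ truncated to $[15, 85]$ by exact
   inverse-CDF sampling.  $V_1$ sets the across-trial spread of covariate
   means, $V_2$ the within-trial spread — their ratio governs how much
   across-trial information competes with within-trial information.
4. Optional trial-level confounding: trials whose *sampled* mean parameter
   exceeds 0.5 (binary) or 50 (continuous) receive an extra additive
   treated-arm log-hazard $\beta_4$ (a "higher dose in high-covariate
   trials" mechanism).  The indicator uses the sampled parameter, not the
   realised empirical mean, because it represents a property of the trial's
   design; the threshold is strict, and under the continuous uniforms the
   boundary has probability zero.
5. Survival: constant baseline hazard $\lambda_0$, linear predictor
   $\beta_{0j} + \beta_1 z + \beta_2 x + \beta_3 x z + \beta_4 y_j z$ with
   $\beta_{0j} \sim U(0, 0.5)$, inverse-transform exponential times, and
   purely administrative censoring at 5 years.

Defaults: $\beta_1 = 1$ (a large treatment effect, hazard ratio 2.7,
appropriate when the event is desirable, e.g. remission), $\beta_2 =
\beta_3 = 0.5$ for a binary covariate and $0.01$ per year for a continuous
one, $\beta_4 = 0.75$ in confounded scenarios, $\lambda_0 = 0.1$ events
per year.  With these values a control-arm patient has roughly a 50%
chance of an event before the 5-year horizon and a treated patient around
90%, giving each trial a realistic mix of events and censorings.  Reading
the exponential parameter as a *mean* survival of 0.1 years instead would
make virtually every patient fail within weeks and the censoring rule
vacuous, which is why the rate reading is the default; `lambda0` is an
ordinary config knob, so either convention is runnable.

Two named presets cover the usual bench sizes: `"large"` ($J = 10$,
$N = 500$) and `"small"` ($J = 5$, $N = 250$); `"large_n250"` is provided
as well because both 250 and 500 circulate as the large-setting trial size
in the literature this bench follows — the summary-level behaviour of the
interaction estimators is nearly unaffected because within- and
across-trial precision scale together with $N$ in fixed-effect fits.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about field data: random (non-administrative) censoring and
staggered entry; non-proportional hazards and time-varying effects;
within-trial confounding; missing covariates (validation rejects them —
there is no imputation machinery); informative trial sizes; ties in event
times (times are continuous; Efron handling covers tied real data but the
bench never stresses it).

## The Monte-Carlo bench

`run_study()` seeds the RNG once with `master_seed`, spawns one seed per
replicate via `sample.int()` so individual replicates are reproducible in
isolation, fits every requested model to the *same* generated dataset
(paired comparisons), and summarises per model and parameter: mean, SD,
mean SE, bias, MSE and the coverage of the 95% Wald intervals against the
generating $\beta_3$.  Datasets containing a trial with no events or a
single arm are regenerated from the next derived seed, with the count
reported.  Non-convergent fits are excluded from summaries (counts
reported); regeneration-instead-of-exclusion can be mimicked by rerunning
with another master seed.  Every summary satisfies the finite-sample
identity $\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{SD}^2 (R-1)/R$, which
the tests check to $10^{-9}$ — it is a pure arithmetic invariant and a
cheap guard against summary bugs.  The raw per-replicate table is always
returned (and written as CSV when `out_dir` is given), so summaries can be
recomputed without refitting.

`replicate_tables()` packages the four standard benchmark grids (binary or
continuous covariate, with or without confounding, large and small
settings, the $V_1/V_2$ combinations).  The package's own acceptance bench
runs the large-setting scenarios at $R = 200$ replicates — enough for
3-SE Monte-Carlo bands of roughly $\pm 0.015$ on a binary-covariate
interaction mean while keeping a full bench run in the minutes range —
whereas published reference studies of this design conventionally use
$R = 1000$ (the `n_reps` default).

Under confounding the bench reproduces the qualitative signature of
ecological bias: $\hat\beta_A$ is severely biased with near-zero coverage,
the fixed-effect $\hat\beta_T$ inherits a substantial share of that bias,
the random-effects $\hat\beta_T$ a smaller share (the heterogeneity term
soaks up part of the trial-level signal), and $\hat\beta_W$ stays unbiased
with nominal coverage.  On the heterogeneity scale, note that variance-
scale summaries ($\tau^2$) are common in meta-analysis reporting; this
package reports the SD $\tau$, and its test bench converts to $\tau^2$
where a variance-scale reference value is being matched.

## Known limitations

* No counting-process input, time-varying covariates, competing risks,
  left truncation, or non-administrative censoring.
* No random effect on the interaction coefficient itself; heterogeneity is
  modelled on the treatment main effect only.
* No proportional-baselines variant, non-PH diagnostics, penalised
  (Firth-type) fits, or Bayesian estimation.
* Aggregate-data trials cannot be mixed in; every trial must contribute
  IPD.
* The $\tau$ SE is an observed-information delta-method quantity; it is
  unreliable near the boundary and reported as `NA` there.
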