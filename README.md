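# ipdinteract

Treatment–covariate interactions in one-stage individual participant data
(IPD) meta-analysis of survival outcomes — estimated so that within-trial
information is separated from across-trial information, because only the
former is safe from ecological bias.

## Who this is for

Meta-analysts with patient-level time-to-event data from several randomised
trials who want to know whether a patient covariate (age, sex, severity)
modifies the treatment effect, and methodologists who want a reproducible
simulation bench for the competing one-stage estimators.

## The models

With trials $j = 1,\dots,J$, treatment $z_{ij} \in \{0,1\}$ and covariate
$x_{ij}$, all models stratify the baseline hazard by trial.  The naive
one-stage model amalgamates the interaction:

$$\lambda_{ij}(t) = \lambda_{0j}(t)\exp\{\beta_1 z_{ij} + \beta_2 x_{ij} + \beta_T\, x_{ij} z_{ij}\}$$

$\hat\beta_T$ blends the patient-level (within-trial) contrast with the
trial-level association between mean covariate $\bar x_j$ and trial
treatment effect — an aggregate comparison vulnerable to trial-level
confounding (e.g. dose).  Centring the covariate within trials separates
the two:

$$\lambda_{ij}(t) = \lambda_{0j}(t)\exp\{\beta_{1j} z_{ij} + \beta_2 x_{ij} + \beta_W (x_{ij}-\bar x_j) z_{ij}\},\qquad \beta_{1j} = \alpha + \beta_A \bar x_j \,(+\, b_{1j})$$

$\beta_W$ is the within-trial interaction (the quantity of clinical
interest), $\beta_A$ the across-trial association, and
$\hat\beta_W - \hat\beta_A$ estimates the magnitude of ecological bias.
The optional $b_{1j} \sim N(0,\tau^2)$ is a trial-level random treatment
effect.  Models are numbered 1–4: amalgamated/separated × fixed/random.
Fixed models are stratified `survival::coxph()` fits; random models
maximise the integrated stratified partial likelihood with adaptive
Gauss–Hermite quadrature (the partial-likelihood kernel is in C++).

The package also provides: validated CSV import/export of IPD tables,
within-trial centring, a two-stage (per-trial + inverse-variance pooling)
comparator, a multi-trial survival-data simulator with optional trial-level
dose confounding, and a Monte-Carlo study runner reporting bias, MSE and
coverage of the interaction estimators.

## Worked example

A bundled generator produces a synthetic five-trial epilepsy-style dataset
(~1225 patients, time to 12-month remission, age as the covariate of
interest).  It is simulated data shaped like a classic IPD meta-analysis —
not the real trials.

```r
library(ipdinteract)
tab <- synthetic_epilepsy_ipd()

fit_model(tab, 1)   # amalgamated interaction
#> One-stage IPD interaction model (amalgamated interaction, fixed treatment effect)
#>    term  estimate       se    ci_low    ci_high        p
#>   treat  0.497900 0.172700  0.159500  0.8363000 0.003928
#>       x -0.002883 0.003455 -0.009655  0.0038890 0.404100
#>  beta_T -0.009040 0.004193 -0.017260 -0.0008225 0.031070
#> loglik = -4587.4983, converged = TRUE

f3 <- fit_model(tab, 3)  # separated interactions
#> One-stage IPD interaction model (separated interaction, fixed treatment effect)
#>    term  estimate       se   ci_low   ci_high         p
#>   treat  0.850400 0.253000  0.35460  1.346000 0.0007746
#>       x -0.006386 0.003905 -0.01404  0.001268 0.1020000
#>  beta_W -0.002453 0.005410 -0.01306  0.008151 0.6503000
#>  beta_A -0.018110 0.006336 -0.03052 -0.005687 0.0042710
#> loglik = -4585.6597, converged = TRUE
```

The amalgamated fit declares a significant age-by-treatment interaction
(`beta_T` = −0.0090 per year, p = 0.031).  Separating the information
shows why: the patient-level interaction is small and non-significant
(`beta_W` = −0.0025, p = 0.65) while the trial-level association is much
larger (`beta_A` = −0.0181) — the "significant" amalgamated interaction is
driven by across-trial (ecological) information, which in this synthetic
dataset is confounded by construction.

```r
ecological_bias(f3)
#> ecological bias (beta_W - beta_A): 0.0157 (SE 0.0082), 95% CI -0.0003 to 0.0317

two_stage_interaction(tab, "DL")$estimate   # agrees with beta_W
#> [1] -0.0006
```

For simulation work:

```r
scn <- scenario_config(J = 10, N = 500, covariate_kind = "binary",
                       V1 = 0.4, beta4 = 0.75)        # dose-confounded scenario
res <- run_study(study_config(scn, models = c(1, 3), n_reps = 200,
                              master_seed = 1))
res$summary   # mean, SD, bias, MSE, coverage per model x parameter
```

A command-line front-end (`inst/cli/ipdmeta.R`) wraps the same functions as
`simulate`, `fit` and `study` subcommands; the methods vignette
(`vignettes/ipd-interactions.Rmd`) documents the models, the simulator's
assumptions and every numerical choice.

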