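#' Scenario configuration for the IPD survival simulator
#'
#' Bundles every data-generating parameter of a simulated multi-trial IPD
#' survival meta-analysis.  Patients in trial j have hazard
#' \deqn{\lambda_{ij}(t) = \lambda_0 \exp(\beta_{0j} + \beta_1 z_{ij} +
#'   \beta_2 x_{ij} + \beta_3 x_{ij} z_{ij} + \beta_4 y_j z_{ij})}
#' with a constant (exponential) baseline rate `lambda0`, a per-trial
#' baseline shift `beta0j ~ U(beta0_range)`, randomised treatment
#' `z ~ Bernoulli(0.5)`, and administrative censoring at `censor_time`.
#' The trial-level confounder indicator `y_j` (e.g. a higher drug dose in
#' some trials) is switched on for trials whose sampled mean covariate
#' exceeds 0.5 (binary x) or 50 (continuous x); `beta4 = 0` disables it.
#'
#' Covariates: for `covariate_kind = "binary"` the trial covariate mean is
#' drawn from U(0.5 - V1, 0.5 + V1) and patients are Bernoulli draws with
#' that mean; for `"continuous"` the trial mean is drawn from
#' U(50 - V1, 50 + V1) and patients from Normal(mean, V2^2) truncated to
#' `trunc_bounds`.  `V1` thus controls across-trial spread of the covariate
#' means and `V2` the within-trial spread of individual values.
#'
#' @param J number of trials.
#' @param N mean trial size; individual sizes are Normal(N, (N/5)^2),
#'   rounded, floored at 10.
#' @param covariate_kind `"binary"` or `"continuous"`.
#' @param V1 half-width of the uniform for the trial covariate means
#'   (in `[0, 0.5]` for binary, `[0, 35]` for continuous).
#' @param V2 within-trial SD of the covariate (continuous kind only).
#' @param beta0_range range of the per-trial baseline log-hazard shift.
#' @param beta1 treatment log hazard ratio at x = 0.
#' @param beta2 covariate main effect (default 0.5 binary, 0.01 continuous).
#' @param beta3 true treatment-covariate interaction (default as `beta2`).
#' @param beta4 trial-level confounder effect on the treated arm
#'   (0 = no confounding; 0.75 in the confounded scenarios).
#' @param lambda0 baseline hazard rate (events per year).
#' @param censor_time administrative censoring horizon (years).
#' @param trunc_bounds truncation interval for the continuous covariate.
#' @param seed optional RNG seed consumed by [generate_dataset()].
#'
#' @return An object of class `scenario_config` (a list).
#' @export
scenario_config <- function(J = 10, N = 500,
                            covariate_kind = c("binary", "continuous"),
                            V1 = 0.4, V2 = 10,
                            beta0_range = c(0, 0.5),
                            beta1 = 1,
                            beta2 = NULL, beta3 = NULL, beta4 = 0,
                            lambda0 = 0.1, censor_time = 5,
                            trunc_bounds = c(15, 85),
                            seed = NULL) {
  covariate_kind <- match.arg(covariate_kind)
  if (is.null(beta2)) beta2 <- if (covariate_kind == "binary") 0.5 else 0.01
  if (is.null(beta3)) beta3 <- if (covariate_kind == "binary") 0.5 else 0.01
  cfg <- list(J = as.integer(J), N = N, covariate_kind = covariate_kind,
              V1 = V1, V2 = V2, beta0_range = beta0_range, beta1 = beta1,
              beta2 = beta2, beta3 = beta3, beta4 = beta4, lambda0 = lambda0,
              censor_time = censor_time, trunc_bounds = trunc_bounds,
              seed = seed)
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with(cfg, {
    if (J < 1) stop("J must be >= 1", call. = FALSE)
    if (N < 10) stop("N must be >= 10", call. = FALSE)
    if (covariate_kind == "binary" && (V1 < 0 || V1 > 0.5)) {
      stop("binary covariate requires 0 <= V1 <= 0.5", call. = FALSE)
    }
    if (covariate_kind == "continuous") {
      if (V1 < 0 || V1 > 35) stop("continuous covariate requires 0 <= V1 <= 35",
                                  call. = FALSE)
      if (V2 <= 0) stop("V2 must be > 0", call. = FALSE)
    }
    if (lambda0 <= 0) stop("lambda0 must be > 0", call. = FALSE)
    if (censor_time <= 0) stop("censor_time must be > 0", call. = FALSE)
  })
  cfg
}

#' Named scenario presets
#'
#' `"large"` is J = 10 trials of mean size 500; `"small"` is J = 5 trials of
#' mean size 250.  `"large_n250"` (J = 10, N = 250) is also provided because
#' the two sizes are both in circulation for the large setting.  Further
#' arguments override preset fields via [scenario_config()].
#'
#' @param name preset name.
#' @param ... overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("large", "small", "large_n250"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    large = list(J = 10, N = 500),
    small = list(J = 5, N = 250),
    large_n250 = list(J = 10, N = 250)
  )
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

#' Read / write scenario configurations as YAML
#'
#' @param cfg a [scenario_config()].
#' @param path file path.
#' @return `read_scenario` returns a [scenario_config()];
#'   `write_scenario` returns `path` invisibly.
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals)
}

#' Sample trial sizes
#'
#' Trial sizes are Normal(N, (N/5)^2) rounded to the nearest integer and
#' floored at 10 to avoid degenerate trials.
#'
#' @param J number of trials.
#' @param N mean trial size.
#' @return Integer vector of length `J`.
#' @export
sample_trial_sizes <- function(J, N) {
  stopifnot(J >= 1, N >= 10)
  pmax(10L, as.integer(round(rnorm(J, mean = N, sd = N / 5))))
}

#' Sample one trial's covariate values
#'
#' Binary: the trial mean is drawn from U(0.5 - V1, 0.5 + V1) and patient
#' values are Bernoulli with that mean.  Continuous: the trial mean is drawn
#' from U(50 - V1, 50 + V1) and patient values from Normal(mean, V2^2)
#' truncated to `cfg$trunc_bounds` (exact inverse-CDF sampling).
#'
#' @param n trial size.
#' @param cfg a [scenario_config()].
#' @return List with `xbar_sampled` (the latent mean parameter) and `x`
#'   (length-`n` covariate values).
#' @export
sample_covariates <- function(n, cfg) {
  if (cfg$covariate_kind == "binary") {
    xbar <- runif(1, 0.5 - cfg$V1, 0.5 + cfg$V1)
    x <- rbinom(n, 1, xbar)
  } else {
    xbar <- runif(1, 50 - cfg$V1, 50 + cfg$V1)
    lo <- pnorm(cfg$trunc_bounds[1], xbar, cfg$V2)
    hi <- pnorm(cfg$trunc_bounds[2], xbar, cfg$V2)
    x <- qnorm(runif(n, lo, hi), xbar, cfg$V2)
  }
  list(xbar_sampled = xbar, x = x)
}

#' Trial-level confounder assignment
#'
#' A trial receives the confounding dose effect (`y_j = 1`) when its sampled
#' mean covariate parameter exceeds 0.5 (binary covariate) or 50
#' (continuous).  The inequality is strict; under the continuous uniforms
#' the boundary has probability zero.
#'
#' @param xbar_sampled the sampled trial mean parameter.
#' @param covariate_kind `"binary"` or `"continuous"`.
#' @return 0 or 1.
#' @export
assign_confounder <- function(xbar_sampled, covariate_kind) {
  threshold <- if (covariate_kind == "binary") 0.5 else 50
  as.numeric(xbar_sampled > threshold)
}

#' Simulate exponential survival times with administrative censoring
#'
#' Latent event times are Exponential with rate
#' `lambda0 * exp(linpred)` (inverse-transform: `T = -log(U) / rate`);
#' follow-up is `min(T, censor_time)` and the event indicator is
#' `T <= censor_time`.  Censoring is purely administrative.
#'
#' @param linpred per-patient log relative hazard.
#' @param lambda0 baseline hazard rate.
#' @param censor_time censoring horizon.
#' @return Data frame with columns `time` and `event`.
#' @export
simulate_survival <- function(linpred, lambda0, censor_time) {
  stopifnot(lambda0 > 0, censor_time > 0)
  latent <- -log(runif(length(linpred))) / (lambda0 * exp(linpred))
  data.frame(time = pmin(latent, censor_time),
             event = as.numeric(latent <= censor_time))
}

#' Generate one simulated IPD meta-analysis dataset
#'
#' Composes the sampling steps: trial sizes; Bernoulli(0.5) treatment
#' allocation; trial covariate means and patient covariates; the trial
#' confounder indicator; per-trial baseline shifts `beta0j ~ U(beta0_range)`;
#' the linear predictor
#' `beta0j + beta1*z + beta2*x + beta3*x*z + beta4*y_j*z`; and exponential
#' survival with administrative censoring.
#'
#' @param cfg a [scenario_config()].  If `cfg$seed` is non-NULL the global
#'   RNG is seeded with it first.
#' @return List with:
#'   \describe{
#'     \item{`table`}{an [ipd_table()].}
#'     \item{`trials`}{per-trial frame: `trial_id`, `n`, `xbar_sampled`,
#'       `x_bar` (empirical), `y`, `beta0j`.}
#'     \item{`truth`}{list echoing the generating parameters, with the target
#'       interaction `beta3`.}
#'   }
#' @export
generate_dataset <- function(cfg) {
  validate_scenario(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sizes <- sample_trial_sizes(cfg$J, cfg$N)
  rows <- vector("list", cfg$J)
  trials <- vector("list", cfg$J)
  for (j in seq_len(cfg$J)) {
    n <- sizes[j]
    z <- rbinom(n, 1, 0.5)
    cov <- sample_covariates(n, cfg)
    y_j <- assign_confounder(cov$xbar_sampled, cfg$covariate_kind)
    beta0j <- runif(1, cfg$beta0_range[1], cfg$beta0_range[2])
    linpred <- beta0j + cfg$beta1 * z + cfg$beta2 * cov$x +
      cfg$beta3 * cov$x * z + cfg$beta4 * y_j * z
    surv <- simulate_survival(linpred, cfg$lambda0, cfg$censor_time)
    rows[[j]] <- data.frame(trial_id = sprintf("trial%02d", j),
                            patient_id = sprintf("p%04d", seq_len(n)),
                            z = z, x = cov$x,
                            time = surv$time, event = surv$event,
                            stringsAsFactors = FALSE)
    trials[[j]] <- data.frame(trial_id = sprintf("trial%02d", j), n = n,
                              xbar_sampled = cov$xbar_sampled,
                              x_bar = mean(cov$x), y = y_j, beta0j = beta0j,
                              stringsAsFactors = FALSE)
  }
  table <- ipd_table(do.call(rbind, rows))
  trials <- do.call(rbind, trials)
  truth <- list(beta1 = cfg$beta1, beta2 = cfg$beta2, beta3 = cfg$beta3,
                beta4 = cfg$beta4, lambda0 = cfg$lambda0,
                beta0j = trials$beta0j, xbar_sampled = trials$xbar_sampled,
                y = trials$y, covariate_kind = cfg$covariate_kind)
  list(table = table, trials = trials, truth = truth)
}
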