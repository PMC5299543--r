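#' Estimate the magnitude of ecological bias
#'
#' From a fitted separated-interaction model, the contrast between the
#' within-trial interaction (`beta_W`) and the across-trial association
#' (`beta_A`) estimates how far the aggregate, trial-level relationship is
#' displaced from the patient-level one, typically by unmeasured trial-level
#' confounding (e.g. dose).  The standard error uses the full linear
#' contrast from the fitted covariance matrix; after within-trial centring
#' the two coefficients are close to uncorrelated, but the covariance term
#' is taken from `vcov`, not assumed zero.
#'
#' @param fit an `ipd_fit` from a separated model containing both `beta_W`
#'   and `beta_A`.
#' @param level confidence level.
#' @return List with `estimate` (`beta_W - beta_A`), `se`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
ecological_bias <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ipd_fit"))
  co <- fit$coefficients
  if (!all(c("beta_W", "beta_A") %in% co$term)) {
    stop("fit must contain both beta_W and beta_A ",
         "(separated model with the across-trial term included)",
         call. = FALSE)
  }
  bw <- co$estimate[co$term == "beta_W"]
  ba <- co$estimate[co$term == "beta_A"]
  V <- fit$vcov[c("beta_W", "beta_A"), c("beta_W", "beta_A")]
  se <- sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2])
  wi <- wald_interval(bw - ba, se, level)
  list(estimate = bw - ba, se = se,
       ci_low = unname(wi["low"]), ci_high = unname(wi["high"]),
       p = unname(wi["p"]))
}

#' Two-stage interaction meta-analysis comparator
#'
#' Stage 1 fits a Cox model `~ z + x + x:z` separately in each trial and
#' keeps the interaction coefficient; stage 2 pools the per-trial
#' interactions by inverse-variance weighting, either common-effect
#' (`"fixed"`) or random-effects with the DerSimonian-Laird moment estimator
#' (`"DL"`).  Because only within-trial contrasts are pooled, the result is
#' free of ecological bias and should closely track the one-stage `beta_W`.
#'
#' Trials in which the interaction is inestimable (constant covariate, a
#' single arm after subsetting, monotone likelihood) are excluded with a
#' warning and counted.
#'
#' @param table an [ipd_table()].
#' @param pooling `"fixed"` or `"DL"`.
#' @param level confidence level.
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`, `p`, `tau2`
#'   (DL only, else 0), `per_trial` (data frame of trial estimates),
#'   `n_excluded`.
#' @export
two_stage_interaction <- function(table, pooling = c("fixed", "DL"),
                                  level = 0.95) {
  stopifnot(inherits(table, "ipd_table"))
  pooling <- match.arg(pooling)
  tabs <- split(as.data.frame(table), table$trial_id)
  rows <- lapply(names(tabs), function(tid) {
    d <- tabs[[tid]]
    out <- data.frame(trial_id = tid, estimate = NA_real_, se = NA_real_,
                      reason = "", stringsAsFactors = FALSE)
    if (var(d$x) == 0) {
      out$reason <- "constant covariate"
      return(out)
    }
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ z + x + z:x, data = d,
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) {
      out$reason <- "fit failed"
      return(out)
    }
    est <- coef(fit)[["z:x"]]
    se <- sqrt(vcov(fit)["z:x", "z:x"])
    if (!is.finite(est) || !is.finite(se) || abs(est) >= .coef_limit) {
      out$reason <- "monotone likelihood"
      return(out)
    }
    out$estimate <- est
    out$se <- se
    out
  })
  per_trial <- do.call(rbind, rows)
  ok <- is.finite(per_trial$estimate)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    warning(n_excluded, " trial(s) excluded from the two-stage pooling (",
            paste(per_trial$trial_id[!ok], collapse = ", "), ")",
            call. = FALSE)
  }
  if (sum(ok) < 2) {
    stop("fewer than 2 trials with an estimable within-trial interaction",
         call. = FALSE)
  }
  rma <- metafor::rma(yi = per_trial$estimate[ok], sei = per_trial$se[ok],
                      method = if (pooling == "fixed") "FE" else "DL",
                      level = 100 * level)
  est <- as.numeric(rma$beta)
  se <- rma$se
  wi <- wald_interval(est, se, level)
  list(estimate = est, se = se,
       ci_low = unname(wi["low"]), ci_high = unname(wi["high"]),
       p = unname(wi["p"]),
       tau2 = if (pooling == "DL") rma$tau2 else 0,
       per_trial = per_trial, n_excluded = n_excluded, pooling = pooling)
}
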