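#' Wald interval and p-value on the log-hazard scale
#'
#' @param estimate point estimate (log hazard ratio scale).
#' @param se standard error, `> 0`.
#' @param level confidence level.
#' @return Named vector `low`, `high`, `p` (two-sided normal).
#' @export
wald_interval <- function(estimate, se, level = 0.95) {
  stopifnot(all(se > 0))
  zq <- qnorm((1 + level) / 2)
  c(low = estimate - zq * se, high = estimate + zq * se,
    p = 2 * pnorm(-abs(estimate / se)))
}

# assemble the standard fit container used by both engines
new_fit_result <- function(estimates, ses, vcov, loglik, converged, n_iter,
                           spec, level, tau = NA_real_, tau_se = NA_real_,
                           boundary = FALSE, warnings = character(0),
                           engine = "coxph") {
  estimates <- unlist(estimates)
  ses <- unlist(ses)
  terms <- names(estimates)
  ci <- t(vapply(terms, function(tm) wald_interval(estimates[[tm]], ses[[tm]], level),
                 numeric(3)))
  coefficients <- data.frame(
    term = terms, estimate = unname(estimates), se = unname(ses),
    ci_low = ci[, "low"], ci_high = ci[, "high"], p = ci[, "p"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(coefficients = coefficients, tau = tau, tau_se = tau_se,
                 loglik = loglik, converged = converged, n_iter = n_iter,
                 vcov = vcov, spec = spec, level = level, boundary = boundary,
                 warnings = warnings, engine = engine),
            class = "ipd_fit")
}

#' @export
print.ipd_fit <- function(x, digits = 4, ...) {
  form <- x$spec$interaction_form
  eff <- x$spec$effect_type
  cat(sprintf("One-stage IPD interaction model (%s interaction, %s treatment effect)\n",
              form, eff))
  co <- x$coefficients
  co[, -1] <- lapply(co[, -1], signif, digits = digits)
  print(co, row.names = FALSE)
  if (!is.na(x$tau)) {
    cat(sprintf("between-trial SD of treatment effect tau = %.4f%s\n", x$tau,
                if (x$boundary) " (boundary)" else ""))
  }
  cat(sprintf("loglik = %.4f, converged = %s\n", x$loglik, x$converged))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# monotone-likelihood guard shared by both engines
.coef_limit <- 15

#' Fit a fixed-effect one-stage interaction model
#'
#' Maximises the Cox partial likelihood stratified by trial (a separate
#' nonparametric baseline hazard per trial), Efron tie handling, through
#' [survival::coxph()].  Standard errors come from the observed information;
#' intervals and p-values are Wald on the log-hazard scale.
#'
#' A coefficient wandering beyond +/-15 is taken as evidence of a monotone
#' (infinite-estimate) likelihood and reported via `converged = FALSE`
#' rather than returned silently.
#'
#' @param table an [ipd_table()].
#' @param spec a [model_spec()] with `effect_type = "fixed"`.
#' @param level confidence level for Wald intervals.
#' @return An object of class `ipd_fit`; see [model_spec()] for term names.
#' @export
fit_fixed <- function(table, spec = model_spec("amalgamated", "fixed"),
                      level = 0.95) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$effect_type != "fixed") {
    stop("fit_fixed requires effect_type = 'fixed'", call. = FALSE)
  }
  des <- build_design(table, spec)
  df <- data.frame(.time = des$time, .event = des$event, .strat = des$strata)
  df <- cbind(df, as.data.frame(des$X))
  fml <- as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(des$X)), collapse = " + "),
    "+ survival::strata(.strat)"
  ))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  est <- coef(fit)
  names(est) <- colnames(des$X)
  V <- vcov(fit)
  dimnames(V) <- list(names(est), names(est))
  ses <- sqrt(diag(V))
  converged <- all(is.finite(est)) && all(abs(est) < .coef_limit)
  if (!converged) {
    warns <- c(warns, "possible monotone likelihood: a coefficient exceeded +/-15")
  }
  new_fit_result(as.list(est), as.list(ses), V,
                 loglik = fit$loglik[2], converged = converged,
                 n_iter = fit$iter, spec = spec, level = level,
                 warnings = warns, engine = "coxph")
}

#' Fit a random-effects one-stage interaction model
#'
#' Fits models with a trial-level normal random effect `b_j ~ N(0, tau^2)` on
#' the treatment coefficient by maximising the integrated stratified partial
#' likelihood: within each trial the Cox partial likelihood is treated as a
#' function of the trial's random deviation `b_j`, which is integrated out
#' by adaptive Gauss-Hermite quadrature (the quadrature grid is re-centred
#' at each trial's conditional mode and scaled by its conditional curvature).
#' The fixed coefficients and `log(tau)` are then maximised by quasi-Newton
#' (`nlminb`), warm-started from the corresponding fixed-effect fit.
#'
#' Standard errors are from the inverse numerical Hessian of the integrated
#' log-likelihood.  `tau` estimates below `1e-5` are flagged as boundary
#' solutions (the model degenerates to the fixed-effect fit there).
#'
#' @param table an [ipd_table()].
#' @param spec a [model_spec()] with `effect_type = "random"`.
#' @param level confidence level for Wald intervals.
#' @param quad_nodes number of Gauss-Hermite nodes (default 15; doubling it
#'   is a useful convergence diagnostic).
#' @param control list overriding `nlminb` control parameters.
#' @return An object of class `ipd_fit` with `tau` filled in.
#' @export
fit_random <- function(table, spec = model_spec("amalgamated", "random"),
                       level = 0.95, quad_nodes = 15, control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$effect_type != "random") {
    stop("fit_random requires effect_type = 'random'", call. = FALSE)
  }
  des <- build_design(table, spec)
  p <- ncol(des$X)

  # per-stratum data sorted by decreasing time (required by the C++ kernel)
  strata <- split(seq_along(des$time), des$strata)
  sdat <- lapply(strata, function(idx) {
    o <- idx[order(des$time[idx], decreasing = TRUE)]
    list(X = des$X[o, , drop = FALSE], z = des$X[o, "treat"],
         event = as.integer(des$event[o]), time = des$time[o])
  })
  gh <- pracma::gaussHermite(quad_nodes)

  # conditional modes are warm-started across objective evaluations (the
  # optimizer moves the parameters slowly, so a couple of Newton steps
  # usually suffice), then polished to 1e-12 so the objective stays
  # deterministic to within quadrature accuracy regardless of history
  modes <- rep(0, length(sdat))

  nll <- function(par) {
    gamma <- par[seq_len(p)]
    # tau is optimized unconstrained on the log scale (box constraints make
    # nlminb crawl on the flat small-tau shelf); the floor only guards the
    # arithmetic far below any distinguishable heterogeneity
    tau <- max(exp(par[p + 1]), 1e-10)
    total <- 0
    for (jj in seq_along(sdat)) {
      s <- sdat[[jj]]
      eta0 <- as.numeric(s$X %*% gamma)
      # conditional mode of b_j by damped Newton on log PL + log prior
      b <- modes[jj]
      g1 <- Inf
      for (it in 1:100) {
        r <- cox_plik_stratum(eta0, s$z, s$event, s$time, b)
        g1 <- r[1, 2] - b / tau^2
        g2 <- r[1, 3] - 1 / tau^2   # < 0 always
        step <- -g1 / g2
        if (!is.finite(step)) break
        step <- max(min(step, 2), -2)
        b <- b + step
        if (abs(step) < 1e-12) break
      }
      modes[jj] <<- b
      r <- cox_plik_stratum(eta0, s$z, s$event, s$time, b)
      sigma <- 1 / sqrt(1 / tau^2 - r[1, 3])
      nodes <- b + sqrt(2) * sigma * gh$x
      llb <- cox_plik_stratum(eta0, s$z, s$event, s$time, nodes)[, 1]
      lg <- log(gh$w) + llb + dnorm(nodes, 0, tau, log = TRUE) + gh$x^2
      m <- max(lg)
      total <- total + log(sqrt(2) * sigma) + m + log(sum(exp(lg - m)))
    }
    -total
  }

  # warm start from the matching fixed-effect model
  fixed_spec <- spec
  fixed_spec$effect_type <- "fixed"
  start_fit <- tryCatch(fit_fixed(table, fixed_spec, level = level),
                        error = function(e) NULL)
  start <- if (!is.null(start_fit) &&
               identical(start_fit$coefficients$term, colnames(des$X))) {
    start_fit$coefficients$estimate
  } else {
    rep(0, p)
  }
  par0 <- c(start, log(0.1))

  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 200, eval.max = 500),
                            control)
  opt <- nlminb(par0, nll, control = ctrl)
  gamma <- opt$par[seq_len(p)]
  tau <- max(exp(opt$par[p + 1]), 1e-10)
  boundary <- tau < 1e-5
  warns <- character(0)

  if (boundary) {
    # at tau ~ 0 the log(tau) direction is flat; take curvature over gamma only
    H <- pracma::hessian(function(g) nll(c(g, opt$par[p + 1])), gamma)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
    tau_se <- NA_real_
  } else {
    H <- pracma::hessian(nll, opt$par)
    Vfull <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
    V <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
    vlt <- Vfull[p + 1, p + 1]
    # delta method from log(tau); a non-positive numerical-Hessian variance
    # (near-flat tau direction) is reported as missing, not as NaN
    tau_se <- if (is.finite(vlt) && vlt > 0) sqrt(vlt) * tau else NA_real_
  }
  dimnames(V) <- list(colnames(des$X), colnames(des$X))
  ses <- sqrt(diag(V))
  converged <- opt$convergence == 0 && all(abs(gamma) < .coef_limit) &&
    all(is.finite(ses))
  if (any(abs(gamma) >= .coef_limit)) {
    warns <- c(warns, "possible monotone likelihood: a coefficient exceeded +/-15")
  }
  if (opt$convergence != 0) {
    warns <- c(warns, paste0("nlminb: ", opt$message))
  }
  est <- as.list(setNames(gamma, colnames(des$X)))
  new_fit_result(est, as.list(ses), V, loglik = -opt$objective,
                 converged = converged, n_iter = opt$iterations, spec = spec,
                 level = level, tau = tau, tau_se = tau_se,
                 boundary = boundary, warnings = warns,
                 engine = "agq_partial_likelihood")
}

#' Fit one of the four canonical models by number
#'
#' Convenience wrapper dispatching to [fit_fixed()] (models 1 and 3) or
#' [fit_random()] (models 2 and 4).
#'
#' @param table an [ipd_table()].
#' @param model integer 1-4 (see [model_spec()]).
#' @param ... passed to [model_spec_number()] and the fitter.
#' @param level confidence level.
#' @param quad_nodes Gauss-Hermite nodes for the random-effects models.
#' @return An `ipd_fit`.
#' @export
fit_model <- function(table, model, level = 0.95, quad_nodes = 15, ...) {
  spec <- model_spec_number(model, ...)
  if (spec$effect_type == "fixed") {
    fit_fixed(table, spec, level = level)
  } else {
    fit_random(table, spec, level = level, quad_nodes = quad_nodes)
  }
}
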