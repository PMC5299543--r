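test_that("random fits match an independent numerical-integration oracle", {
  dat <- sim_ipd(71, J = 6, N = 60, beta4 = 0.75)
  fit <- fit_model(dat$table, 2)
  expect_true(fit$converged)
  oracle <- oracle_fit_random(dat$table, model_spec("amalgamated", "random"),
                              start = c(fit$coefficients$estimate, log(fit$tau)))
  expect_equal(setNames(fit$coefficients$estimate, fit$coefficients$term),
               oracle$coef, tolerance = 5e-3)
  expect_equal(fit$tau, oracle$tau, tolerance = 5e-3)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
})

test_that("without heterogeneity the random model collapses to the fixed one", {
  dat <- sim_ipd(72, J = 8, N = 150, beta4 = 0)  # no confounding, tau = 0
  ff <- fit_model(dat$table, 1)
  fr <- fit_model(dat$table, 2)
  expect_true(fr$converged)
  expect_lt(fr$tau, 0.12)
  expect_equal(fr$coefficients$estimate, ff$coefficients$estimate,
               tolerance = 1e-2)
  if (fr$boundary) {
    expect_true(fr$converged)
    expect_lt(fr$tau, 1e-5)
  }
})

test_that("doubling the quadrature nodes leaves the fit unchanged", {
  dat <- sim_ipd(73, J = 6, N = 80, beta4 = 0.75)
  f15 <- fit_model(dat$table, 2, quad_nodes = 15)
  f30 <- fit_model(dat$table, 2, quad_nodes = 30)
  expect_lt(abs(f30$loglik - f15$loglik) / abs(f15$loglik), 1e-4)
  expect_lt(max(abs(f30$coefficients$estimate - f15$coefficients$estimate) /
                  (1 + abs(f15$coefficients$estimate))), 1e-4)
  expect_lt(abs(f30$tau - f15$tau) / (1 + f15$tau), 1e-4)
})

test_that("the Poisson re-expression route agrees with the partial-likelihood route", {
  skip_if_not_installed("glmmTMB")
  library(survival)
  dat <- sim_ipd(74, J = 6, N = 60, beta4 = 0.75)
  d <- as.data.frame(dat$table)
  # exact re-expression: follow-up split at each trial's distinct event times,
  # log-link event model with log interval-length offset, one baseline
  # parameter per trial-by-interval cell (zero-event tail cells drop out of
  # the likelihood exactly)
  sp <- do.call(rbind, lapply(split(d, d$trial_id), function(dd) {
    cuts <- sort(unique(dd$time[dd$event == 1]))
    s <- survSplit(Surv(time, event) ~ ., data = dd, cut = cuts,
                   episode = "interval")
    s$dt <- s$time - s$tstart
    s
  }))
  sp$cell <- interaction(sp$trial_id, sp$interval, drop = TRUE)
  ev <- tapply(sp$event, sp$cell, sum)
  sp <- sp[ev[sp$cell] > 0, ]
  sp$cell <- droplevels(sp$cell)

  # fixed-effect equivalence is exact (Poisson ML profiles to Breslow's
  # partial likelihood; simulated times are untied)
  gf <- glm(event ~ -1 + cell + z + x + z:x, family = poisson, data = sp,
            offset = log(dt))
  cf <- coxph(Surv(time, event) ~ z + x + z:x + strata(trial_id), data = d,
              ties = "breslow")
  expect_equal(unname(coef(gf)[c("z", "x", "z:x")]), unname(coef(cf)),
               tolerance = 1e-6)

  # mixed-model version (Laplace) against our integrated partial likelihood:
  # different likelihood factorisations, so agreement is approximate
  gm <- glmmTMB::glmmTMB(event ~ -1 + cell + z + x + z:x + (0 + z | trial_id),
                         family = poisson, data = sp, offset = log(dt))
  fe <- glmmTMB::fixef(gm)$cond[c("z", "x", "z:x")]
  fr <- fit_model(dat$table, 2)
  se <- fr$coefficients$se
  expect_true(all(abs(unname(fe) - fr$coefficients$estimate) < 0.5 * se))
  tau_tmb <- sqrt(unlist(glmmTMB::VarCorr(gm)$cond))
  expect_lt(abs(fr$tau - tau_tmb), 0.2)
})

test_that("model 4 separates the interactions under confounding", {
  dat <- sim_ipd(75, J = 8, N = 120, beta4 = 0.75)
  f4 <- fit_model(dat$table, 4)
  expect_true(f4$converged)
  co <- setNames(f4$coefficients$estimate, f4$coefficients$term)
  se <- setNames(f4$coefficients$se, f4$coefficients$term)
  # within-trial estimate near truth, across-trial estimate inflated by the
  # unmeasured dose effect
  expect_lt(abs(co["beta_W"] - 0.5), 3 * se["beta_W"])
  expect_gt(co["beta_A"], co["beta_W"])
  eb <- ecological_bias(f4)
  expect_equal(eb$estimate, unname(co["beta_W"] - co["beta_A"]))
  expect_lt(eb$estimate, 0)
})
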