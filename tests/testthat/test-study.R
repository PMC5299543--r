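test_that("performance metrics match hand arithmetic", {
  est <- c(0.4, 0.5, 0.5, 0.6, 0.5)
  reps <- data.frame(model = 1, term = "beta_T", estimate = est, se = 0.05,
                     ci_low = est - 0.1, ci_high = est + 0.1, converged = TRUE)
  s <- summarize_performance(reps, truth = 0.5)
  expect_equal(s$mean, 0.5)
  expect_equal(s$bias, 0, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(0.02 / 4), tolerance = 1e-10)  # 0.07071
  expect_equal(s$mse, 0.004, tolerance = 1e-12)
  expect_equal(s$coverage, 1)
  expect_equal(s$n_used, 5L)

  # all-exact estimates: degenerate summary
  reps2 <- reps
  reps2$estimate <- 0.5
  s2 <- summarize_performance(reps2, 0.5)
  expect_equal(s2[, c("bias", "mse", "sd")], data.frame(bias = 0, mse = 0, sd = 0))

  # non-converged replicates are excluded and counted
  reps$converged[1] <- FALSE
  s3 <- summarize_performance(reps, 0.5)
  expect_equal(s3$n_used, 4L)
  expect_equal(s3$n_excluded, 1L)
  expect_equal(s3$mean, mean(est[-1]))
  reps$converged <- FALSE
  expect_error(summarize_performance(reps, 0.5), "no converged")
})

test_that("replicates are deterministic, paired across models, and archived", {
  scn <- scenario_config(J = 4, N = 60, covariate_kind = "binary", V1 = 0.4)
  cfg <- study_config(scn, models = c(1, 3), n_reps = 4, master_seed = 99)
  dir1 <- withr::local_tempdir()
  r1 <- run_study(cfg, out_dir = dir1)
  r2 <- run_study(cfg)
  expect_identical(r1$replicates, r2$replicates)
  expect_true(file.exists(file.path(dir1, "replicates.csv")))
  # summaries are a pure function of the archive
  arch <- read.csv(file.path(dir1, "replicates.csv"))
  expect_equal(summarize_performance(arch, scn$beta3)$mean, r1$summary$mean)
  # both models were fitted to the same replicate datasets
  by_rep <- split(r1$replicates, r1$replicates$rep)
  for (d in by_rep) expect_length(unique(d$rep_seed), 1L)
  # a single model rerun on a replicate seed reproduces its row
  row <- run_replicate(scn, 1, r1$replicates$rep_seed[1])
  expect_equal(row$estimate,
               r1$replicates$estimate[r1$replicates$model == 1 &
                                        r1$replicates$rep == 1])
})

test_that("single-replicate summaries flag the undefined spread", {
  scn <- scenario_config(J = 3, N = 50, covariate_kind = "binary", V1 = 0.4)
  res <- run_study(study_config(scn, models = 1, n_reps = 1, master_seed = 5))
  expect_equal(res$summary$sd, 0)
  expect_true(res$summary$sd_flag)
  expect_equal(res$summary$mean, res$replicates$estimate)
})

test_that("the Monte-Carlo MSE identity holds on every summary cell", {
  scn <- scenario_config(J = 4, N = 60, covariate_kind = "binary", V1 = 0.4,
                         beta4 = 0.75)
  res <- run_study(study_config(scn, models = c(1, 3), n_reps = 20,
                                master_seed = 42))
  s <- res$summary[res$summary$term != "tau", ]
  R <- s$n_used
  expect_equal(s$mse, s$bias^2 + s$sd^2 * (R - 1) / R, tolerance = 1e-9)
})

test_that("null interaction scenarios are calibrated", {
  scn <- scenario_config(J = 5, N = 100, covariate_kind = "binary", V1 = 0.4,
                         beta3 = 0)
  res <- run_study(study_config(scn, models = 1, n_reps = 200, master_seed = 77))
  reps <- res$replicates
  expect_gte(mean(abs(reps$estimate) < 4 * reps$se), 0.99)
  # coverage of the true null value within the exact 99% binomial band
  cv <- res$summary$coverage
  band <- qbinom(c(0.005, 0.995), 200, 0.95) / 200
  expect_gte(cv, band[1])
  expect_lte(cv, band[2])
})

test_that("benchmark grids have the published scenario structure", {
  t1 <- replicate_tables("table1", n_reps = 2, master_seed = 3)
  # 4 scenarios x (model 1: beta_T; model 3: beta_W, beta_A)
  expect_equal(nrow(t1), 4 * 3)
  expect_setequal(unique(t1$size), c("large", "small"))
  expect_setequal(unique(t1$V1), c(0.4, 0.2))
  expect_setequal(unique(t1$term), c("beta_T", "beta_W", "beta_A"))
  expect_true(all(is.na(t1$V2)))

  t3 <- replicate_tables("table3", n_reps = 1, master_seed = 3)
  # 4 scenarios x models 1-4 -> beta_T x2, tau x2, beta_W x2, beta_A x2
  expect_equal(nrow(t3), 4 * 8)
  expect_setequal(unique(t3$model), 1:4)
  expect_true(all(t3$sd_flag))
})
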