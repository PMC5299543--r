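test_that("trial sizes follow Normal(N, (N/5)^2) with a floor at 10", {
  set.seed(11)
  sizes <- sample_trial_sizes(10000, 500)
  expect_length(sizes, 10000L)
  # mean within 3 SE of 500, SD within 5% of 100
  expect_lt(abs(mean(sizes) - 500), 3 * 100 / sqrt(10000))
  expect_lt(abs(sd(sizes) - 100) / 100, 0.05)

  set.seed(12)
  tiny <- sample_trial_sizes(500, 10)  # draws below 10 are common here
  expect_true(all(tiny >= 10))
  expect_true(any(tiny == 10))
  expect_length(sample_trial_sizes(1, 100), 1L)
})

test_that("covariate sampling matches its declared distributions", {
  set.seed(21)
  cfg <- scenario_config(covariate_kind = "binary", V1 = 0)
  expect_equal(sample_covariates(5, cfg)$xbar_sampled, 0.5)

  cfg <- scenario_config(covariate_kind = "continuous", V1 = 20, V2 = 5)
  s <- sample_covariates(10000, cfg)
  expect_true(all(s$x >= 15 & s$x <= 85))
  # truncation negligible at these settings
  expect_lt(abs(mean(s$x) - s$xbar_sampled), 3 * 5 / sqrt(10000))

  cfg <- scenario_config(covariate_kind = "continuous", V1 = 20, V2 = 1e-6)
  s <- sample_covariates(100, cfg)
  expect_equal(s$x, rep(s$xbar_sampled, 100), tolerance = 1e-4)
})

test_that("the confounder indicator switches strictly above the threshold", {
  expect_equal(assign_confounder(0.7, "binary"), 1)
  expect_equal(assign_confounder(0.3, "binary"), 0)
  expect_equal(assign_confounder(0.5, "binary"), 0)
  expect_equal(assign_confounder(50, "continuous"), 0)
  expect_equal(assign_confounder(50.001, "continuous"), 1)
  # symmetric trial-mean law at V1 = 0.4 puts half the trials above 0.5
  set.seed(22)
  cfg <- scenario_config(covariate_kind = "binary", V1 = 0.4)
  y <- replicate(2000, assign_confounder(sample_covariates(1, cfg)$xbar_sampled,
                                         "binary"))
  expect_lt(abs(mean(y) - 0.5), 3 * 0.5 / sqrt(2000))
})

test_that("latent event times are exponential with the stated rate", {
  set.seed(31)
  n <- 1e5
  s <- simulate_survival(rep(0, n), lambda0 = 0.1, censor_time = 1e9)
  expect_lt(abs(mean(s$time) - 10), 3 * 10 / sqrt(n))
  ks <- suppressWarnings(ks.test(s$time, "pexp", 0.1))
  expect_gt(ks$p.value, 0.01)
  # a non-zero linear predictor scales the rate multiplicatively
  s2 <- simulate_survival(rep(log(2), n), lambda0 = 0.1, censor_time = 1e9)
  ks2 <- suppressWarnings(ks.test(s2$time, "pexp", 0.2))
  expect_gt(ks2$p.value, 0.01)

  s3 <- simulate_survival(rep(0, 1000), 0.1, censor_time = 1e-4)
  expect_true(all(s3$event == 0))
  expect_true(all(s3$time == 1e-4))
})

test_that("generated datasets satisfy the structural invariants", {
  for (kind in c("binary", "continuous")) {
    dat <- sim_ipd(41, J = 8, N = 200, kind = kind, beta4 = 0.75)
    tab <- dat$table
    expect_true(all(tab$time > 0 & tab$time <= 5))
    expect_true(all(tab$event %in% c(0, 1)))
    # administrative censoring only
    expect_true(all(tab$time[tab$event == 0] == 5))
    expect_true(all(tab$time[tab$event == 1] < 5))
    if (kind == "binary") {
      expect_true(all(tab$x %in% c(0, 1)))
    } else {
      expect_true(all(tab$x >= 15 & tab$x <= 85))
    }
    # 1:1 allocation within each trial (3-SE binomial band)
    alloc <- tapply(tab$z, tab$trial_id, mean)
    n_j <- tapply(tab$z, tab$trial_id, length)
    expect_true(all(abs(alloc - 0.5) < 3 * 0.5 / sqrt(n_j)))
    # truth record is consistent with the trial frame
    expect_equal(dat$trials$y,
                 as.numeric(dat$trials$xbar_sampled >
                              (if (kind == "binary") 0.5 else 50)))
    expect_equal(dat$truth$beta3, if (kind == "binary") 0.5 else 0.01)
  }
})

test_that("arms are exchangeable when every effect is switched off", {
  set.seed(51)
  scn <- scenario_config(J = 1, N = 4000, covariate_kind = "binary",
                         V1 = 0.4, beta1 = 0, beta2 = 0, beta3 = 0,
                         beta0_range = c(0, 0), censor_time = 1e9)
  dat <- generate_dataset(scn)
  ks <- suppressWarnings(
    ks.test(dat$table$time[dat$table$z == 1], dat$table$time[dat$table$z == 0]))
  expect_gt(ks$p.value, 0.01)
  ks0 <- suppressWarnings(ks.test(dat$table$time, "pexp", 0.1))
  expect_gt(ks0$p.value, 0.01)
})

test_that("scenario configs validate and round-trip through YAML", {
  expect_error(scenario_config(J = 0), "J")
  expect_error(scenario_config(covariate_kind = "binary", V1 = 0.6), "V1")
  expect_error(scenario_config(covariate_kind = "continuous", V2 = 0), "V2")
  expect_error(scenario_config(lambda0 = 0), "lambda0")
  cfg <- scenario_preset("small", covariate_kind = "continuous", V1 = 10,
                         V2 = 5, beta4 = 0.75)
  expect_equal(cfg$J, 5L)
  expect_equal(cfg$N, 250)
  expect_equal(cfg$beta2, 0.01)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  back <- read_scenario(path)
  expect_equal(unclass(back), unclass(cfg))
})
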