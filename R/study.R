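#' Monte-Carlo study configuration
#'
#' @param scenario a [scenario_config()] describing the data-generating
#'   process.
#' @param models integer vector, subset of 1:4 (see [model_spec()]).
#' @param n_reps number of simulation replicates (1000 for a full run;
#'   desk-scale checks use 200).
#' @param master_seed seed for the whole study; per-replicate seeds are
#'   spawned from it (see [run_study()]).
#' @param ci_level confidence level used for the coverage metric.
#' @param quad_nodes Gauss-Hermite nodes for random-effects fits.
#' @return Object of class `study_config`.
#' @export
study_config <- function(scenario, models = c(1, 3), n_reps = 1000,
                         master_seed = 1, ci_level = 0.95, quad_nodes = 15) {
  stopifnot(inherits(scenario, "scenario_config"), n_reps >= 1,
            length(models) >= 1, all(models %in% 1:4))
  structure(list(scenario = scenario, models = as.integer(models),
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed),
                 ci_level = ci_level, quad_nodes = quad_nodes),
            class = "study_config")
}

# a dataset is usable when every trial has both arms and at least one event
.dataset_ok <- function(table) {
  ev <- tapply(table$event, table$trial_id, sum)
  arms <- tapply(table$z, table$trial_id, function(z) length(unique(z)))
  all(ev >= 1) && all(arms == 2)
}

#' Run one simulation replicate
#'
#' Generates one IPD meta-analysis dataset from `scenario` under `rep_seed`
#' and fits every requested model to the *same* dataset (a paired
#' comparison).  Datasets with a pathological trial (no events, or a single
#' arm) are regenerated with `rep_seed + k`, `k = 1, 2, ...`; the number of
#' regenerations is reported.
#'
#' @param scenario a [scenario_config()].
#' @param models integer vector, subset of 1:4.
#' @param rep_seed replicate seed.
#' @param ci_level confidence level.
#' @param quad_nodes Gauss-Hermite nodes for random-effects fits.
#' @param max_tries regeneration budget for pathological datasets.
#' @return Data frame with one row per model x parameter: `model`, `term`
#'   (`beta_T`, `beta_W`, `beta_A` or `tau`), `estimate`, `se`, `ci_low`,
#'   `ci_high`, `converged`, plus replicate bookkeeping (`rep_seed`,
#'   `n_regenerated`, `truth`).
#' @export
run_replicate <- function(scenario, models, rep_seed, ci_level = 0.95,
                          quad_nodes = 15, max_tries = 25) {
  n_regen <- 0L
  dat <- NULL
  scn <- scenario
  scn$seed <- NULL
  for (k in 0:max_tries) {
    set.seed(rep_seed + k)
    cand <- generate_dataset(scn)
    if (.dataset_ok(cand$table)) {
      dat <- cand
      n_regen <- k
      break
    }
  }
  if (is.null(dat)) {
    stop("could not generate a usable dataset in ", max_tries + 1, " attempts",
         call. = FALSE)
  }
  interaction_terms <- c("beta_T", "beta_W", "beta_A")
  rows <- lapply(models, function(m) {
    fit <- tryCatch(
      suppressWarnings(fit_model(dat$table, m, level = ci_level,
                                 quad_nodes = quad_nodes)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      terms <- if (m %in% c(1, 2)) "beta_T" else c("beta_W", "beta_A")
      if (m %in% c(2, 4)) terms <- c(terms, "tau")
      return(data.frame(model = m, term = terms, estimate = NA_real_,
                        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    co <- fit$coefficients
    co <- co[co$term %in% interaction_terms, , drop = FALSE]
    out <- data.frame(model = m, term = co$term, estimate = co$estimate,
                      se = co$se, ci_low = co$ci_low, ci_high = co$ci_high,
                      converged = fit$converged, stringsAsFactors = FALSE)
    if (!is.na(fit$tau)) {
      out <- rbind(out, data.frame(model = m, term = "tau",
                                   estimate = fit$tau, se = fit$tau_se,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   converged = fit$converged,
                                   stringsAsFactors = FALSE))
    }
    out
  })
  res <- do.call(rbind, rows)
  res$rep_seed <- rep_seed
  res$n_regenerated <- n_regen
  res$truth <- scenario$beta3
  res
}

#' Summarise estimator performance over replicates
#'
#' Computes, per model and parameter, the Monte-Carlo mean and SD of the
#' estimates, the mean standard error, bias (mean minus truth), mean squared
#' error, and the coverage of the Wald intervals (fraction of replicates
#' whose CI contains the generating value).  Only converged replicates enter
#' a cell; the exclusion count is reported.  The heterogeneity SD `tau` has
#' no generating analogue in these scenarios, so its bias, MSE and coverage
#' are `NA`.
#'
#' @param replicates the row-bound output of [run_replicate()].
#' @param truth the generating interaction value (`beta3`), used for every
#'   interaction parameter.
#' @return Data frame with one row per model x parameter:
#'   `model`, `term`, `n_used`, `n_excluded`, `mean`, `sd`, `mean_se`,
#'   `bias`, `mse`, `coverage`, `sd_flag` (TRUE when fewer than 2 usable
#'   replicates made the SD undefined; it is then reported as 0).
#' @export
summarize_performance <- function(replicates, truth) {
  cells <- split(replicates, list(replicates$model, replicates$term),
                 drop = TRUE)
  rows <- lapply(cells, function(d) {
    ok <- d$converged & is.finite(d$estimate)
    n_used <- sum(ok)
    if (n_used == 0) {
      stop("no converged replicates for model ", d$model[1], ", term ",
           d$term[1], call. = FALSE)
    }
    est <- d$estimate[ok]
    sd_flag <- n_used < 2
    sdv <- if (sd_flag) 0 else sd(est)
    is_tau <- d$term[1] == "tau"
    data.frame(
      model = d$model[1], term = d$term[1],
      n_used = n_used, n_excluded = sum(!ok),
      mean = mean(est), sd = sdv,
      mean_se = mean(d$se[ok]),
      bias = if (is_tau) NA_real_ else mean(est) - truth,
      mse = if (is_tau) NA_real_ else mean((est - truth)^2),
      coverage = if (is_tau) NA_real_ else
        mean(d$ci_low[ok] <= truth & truth <= d$ci_high[ok]),
      sd_flag = sd_flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a Monte-Carlo simulation study
#'
#' Seeds R's RNG once with `master_seed`, spawns one seed per replicate via
#' `sample.int(2^31 - 64, n_reps)`, and loops [run_replicate()] over them,
#' so any individual replicate can be reproduced from its spawned seed.
#' Summaries are a pure function of the returned replicate table and can be
#' recomputed without refitting.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory; when given, `replicates.csv` (the raw
#'   per-replicate archive) and `summary.csv` are written there.
#' @param progress print a progress line every 50 replicates.
#' @return List with `summary` (see [summarize_performance()]),
#'   `replicates` (raw archive), `n_regenerated` (total pathological
#'   datasets regenerated), and `config`.
#' @export
run_study <- function(cfg, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$master_seed)
  seeds <- sample.int(2147483583L, cfg$n_reps)  # 2^31 - 65, room for +k regen
  reps <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    reps[[r]] <- run_replicate(cfg$scenario, cfg$models, seeds[r],
                               ci_level = cfg$ci_level,
                               quad_nodes = cfg$quad_nodes)
    reps[[r]]$rep <- r
    if (progress && r %% 50 == 0) {
      message("replicate ", r, "/", cfg$n_reps)
    }
  }
  replicates <- do.call(rbind, reps)
  summary <- summarize_performance(replicates, cfg$scenario$beta3)
  out <- list(summary = summary, replicates = replicates,
              n_regenerated = sum(replicates$n_regenerated[!duplicated(replicates$rep)]),
              config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(replicates, file.path(out_dir, "replicates.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  out
}

# scenario grids behind the four benchmark summary tables
.table_grids <- list(
  table1 = list(kind = "binary", beta4 = 0, models = c(1, 3),
                grid = expand.grid(size = c("large", "small"), V1 = c(0.4, 0.2),
                                   stringsAsFactors = FALSE)),
  table2 = list(kind = "continuous", beta4 = 0, models = c(1, 3),
                grid = expand.grid(size = c("large", "small"),
                                   V1 = c(20, 10), V2 = c(10, 5),
                                   stringsAsFactors = FALSE)),
  table3 = list(kind = "binary", beta4 = 0.75, models = 1:4,
                grid = expand.grid(size = c("large", "small"), V1 = c(0.4, 0.2),
                                   stringsAsFactors = FALSE)),
  table4 = list(kind = "continuous", beta4 = 0.75, models = 1:4,
                grid = expand.grid(size = c("large", "small"),
                                   V1 = c(20, 10), V2 = c(10, 5),
                                   stringsAsFactors = FALSE))
)

#' Replicate a benchmark scenario grid
#'
#' Runs the full scenario grid of one of the four standard summary tables:
#' binary or continuous covariate, with or without trial-level confounding,
#' over the large (J = 10, N = 500) and small (J = 5, N = 250) settings and
#' the V1 (and V2) values of that grid.  Returns one summary row per
#' scenario x model x parameter for side-by-side comparison.
#'
#' @param preset `"table1"` (binary, no confounding), `"table2"`
#'   (continuous, no confounding), `"table3"` (binary, confounding) or
#'   `"table4"` (continuous, confounding).
#' @param n_reps replicates per scenario.
#' @param master_seed study master seed (each scenario derives its own
#'   sub-seed from it).
#' @param ... passed to [study_config()] (e.g. `quad_nodes`).
#' @return Data frame: `size`, `V1`, `V2` (continuous only), then the
#'   [summarize_performance()] columns.
#' @export
replicate_tables <- function(preset = c("table1", "table2", "table3", "table4"),
                             n_reps = 200, master_seed = 1, ...) {
  preset <- match.arg(preset)
  tg <- .table_grids[[preset]]
  rows <- vector("list", nrow(tg$grid))
  for (i in seq_len(nrow(tg$grid))) {
    g <- tg$grid[i, ]
    scn <- scenario_preset(g$size, covariate_kind = tg$kind, V1 = g$V1,
                           V2 = if (tg$kind == "continuous") g$V2 else 10,
                           beta4 = tg$beta4)
    cfg <- study_config(scn, models = tg$models, n_reps = n_reps,
                        master_seed = master_seed + i, ...)
    s <- run_study(cfg)$summary
    s$size <- g$size
    s$V1 <- g$V1
    s$V2 <- if (tg$kind == "continuous") g$V2 else NA_real_
    rows[[i]] <- s
  }
  out <- do.call(rbind, rows)
  front <- c("size", "V1", "V2")
  out[, c(front, setdiff(names(out), front))]
}
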