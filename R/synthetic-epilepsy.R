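#' Synthetic epilepsy-style IPD fixture
#'
#' Generates a wholly synthetic dataset shaped like a five-trial epilepsy
#' monotherapy IPD meta-analysis (about 1225 patients): treatment is one of
#' two antiepileptic drugs, the outcome is time to 12-month remission
#' (administratively censored at 5 years), and three patient covariates are
#' carried — `x` (age at randomisation, years), `etype` (generalised = 1 vs
#' partial = 0 epilepsy) and `logsz` (log seizure count in the 6 months
#' before randomisation).  Trial mean ages differ so that within- and
#' across-trial age-by-treatment information can diverge; one trial enrols
#' only partial-epilepsy patients, mimicking a trial with no within-trial
#' information on that covariate.
#'
#' The data are simulated, not real: numbers produced from this fixture
#' exercise the modelling workflow but do not reproduce any published
#' analysis.
#'
#' @param seed RNG seed.
#' @return An [ipd_table()] with extra covariates `etype` and `logsz`.
#' @export
synthetic_epilepsy_ipd <- function(seed = 20160901) {
  set.seed(seed)
  sizes <- c(230, 312, 151, 243, 289)
  mean_age <- c(24, 31, 38, 45, 52)
  p_gen <- c(0.45, 0.35, 0.30, 0.0, 0.25)  # trial 4: partial-only
  rows <- vector("list", 5L)
  for (j in 1:5) {
    n <- sizes[j]
    z <- rbinom(n, 1, 0.5)
    age <- pmin(pmax(rnorm(n, mean_age[j], 12), 5), 80)
    etype <- rbinom(n, 1, p_gen[j])
    logsz <- rnorm(n, 1.6, 1.0)
    # hazard of attaining remission; a mild within-trial age interaction and
    # a stronger across-trial (trial-mean) association stand in for
    # trial-level confounding
    lp <- 0.1 * z - 0.004 * age - 0.15 * etype - 0.05 * logsz -
      0.006 * (age - mean(age)) * z - 0.010 * (mean(age) - 38) * z
    surv <- simulate_survival(lp, lambda0 = 0.35, censor_time = 5)
    rows[[j]] <- data.frame(trial_id = paste0("epi", j),
                            patient_id = sprintf("p%03d", seq_len(n)),
                            z = z, x = age, time = surv$time,
                            event = surv$event, etype = etype, logsz = logsz,
                            stringsAsFactors = FALSE)
  }
  ipd_table(do.call(rbind, rows), extra_covariates = c("etype", "logsz"))
}
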