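#' Model specification for one-stage interaction models
#'
#' The four canonical one-stage stratified Cox specifications are indexed by
#' the interaction form and the treatment-effect type:
#'
#' * model 1 — `amalgamated`, `fixed`: regressors `z`, `x`, `x*z`; the
#'   coefficient on `x*z` (`beta_T`) blends within- and across-trial
#'   information.
#' * model 2 — `amalgamated`, `random`: as model 1 with a trial-level normal
#'   random effect on the treatment coefficient, SD `tau`.
#' * model 3 — `separated`, `fixed`: regressors `z`, `x`,
#'   `(x - xbar_j) * z` (`beta_W`, the within-trial interaction) and
#'   `xbar_j * z` (`beta_A`, the across-trial association).
#' * model 4 — `separated`, `random`: as model 3 plus the random treatment
#'   effect.
#'
#' All four stratify the baseline hazard by trial.  The covariate main
#' effect is common across trials by default (`adjustment = "common"`);
#' `"per_trial"` gives each trial its own coefficient.  For the separated
#' form, `include_across_term = FALSE` drops the `xbar_j * z` term (the
#' within-trial interaction keeps its interpretation).
#'
#' @param interaction_form `"amalgamated"` or `"separated"`.
#' @param effect_type `"fixed"` or `"random"` treatment effect.
#' @param adjustment `"common"` or `"per_trial"` covariate main effect.
#' @param include_across_term keep the trial-mean-by-treatment term
#'   (separated form only).
#' @param extra_adjusters names of additional covariate columns entered with
#'   common coefficients.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(interaction_form = c("amalgamated", "separated"),
                       effect_type = c("fixed", "random"),
                       adjustment = c("common", "per_trial"),
                       include_across_term = TRUE,
                       extra_adjusters = character(0)) {
  spec <- list(interaction_form = match.arg(interaction_form),
               effect_type = match.arg(effect_type),
               adjustment = match.arg(adjustment),
               include_across_term = isTRUE(include_across_term),
               extra_adjusters = extra_adjusters)
  class(spec) <- "model_spec"
  spec
}

#' @rdname model_spec
#' @param model integer 1-4 selecting one of the canonical specifications.
#' @param ... further arguments passed to [model_spec()].
#' @export
model_spec_number <- function(model, ...) {
  stopifnot(model %in% 1:4)
  model_spec(
    interaction_form = if (model %in% c(1, 2)) "amalgamated" else "separated",
    effect_type = if (model %in% c(1, 3)) "fixed" else "random",
    ...
  )
}

#' Build the regression design for a model specification
#'
#' Expands an [ipd_table()] into named regressor columns, the stratum labels
#' (trial ids: each trial keeps its own baseline hazard), and the survival
#' outcome.  For the separated form the covariate is centred within trials
#' internally; `(x - xbar_j) * z` and `xbar_j * z` are then orthogonal within
#' trials, which is what disentangles the within- from the across-trial
#' interaction.
#'
#' Degenerate designs are resolved here: if all trials share the same
#' covariate mean the `xbar_j * z` column is collinear with `z` and is
#' dropped with a warning; if the covariate is constant within every trial
#' the separated form has no within-trial information and building fails.
#'
#' @param table an [ipd_table()].
#' @param spec a [model_spec()].
#' @return A list: `X` (regressor matrix with named columns), `strata`
#'   (factor), `time`, `event`, `terms` (term-role map), `trials`
#'   (per-trial summary from [centre_covariate()]), `dropped` (names of
#'   dropped collinear terms).
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(table, "ipd_table"), inherits(spec, "model_spec"))
  cen <- withCallingHandlers(
    centre_covariate(table),
    warning = function(w) {
      if (spec$interaction_form == "amalgamated") invokeRestart("muffleWarning")
    }
  )
  tab <- cen$table
  trials <- cen$trials
  dropped <- character(0)

  cols <- list(treat = tab$z)
  if (spec$adjustment == "common") {
    cols$x <- tab$x
  } else {
    for (tid in trials$trial_id) {
      cols[[paste0("x.", tid)]] <- tab$x * (tab$trial_id == tid)
    }
  }
  if (spec$interaction_form == "amalgamated") {
    cols$beta_T <- tab$x * tab$z
  } else {
    if (all(trials$constant_x)) {
      stop("no within-trial information: the covariate is constant in every trial",
           call. = FALSE)
    }
    cols$beta_W <- tab$x_centred * tab$z
    if (spec$include_across_term) {
      if (var(trials$x_bar) < 1e-12 * (1 + mean(trials$x_bar))^2) {
        warning("all trials share the same covariate mean: ",
                "across-trial term is collinear with treatment and is dropped",
                call. = FALSE)
        dropped <- "beta_A"
      } else {
        cols$beta_A <- tab$x_bar * tab$z
      }
    }
  }
  for (col in spec$extra_adjusters) {
    if (!col %in% names(tab)) {
      stop("extra adjuster '", col, "' not found in the IPD table", call. = FALSE)
    }
    cols[[col]] <- as.numeric(tab[[col]])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, strata = factor(tab$trial_id), time = tab$time,
       event = tab$event, terms = names(cols), trials = trials,
       dropped = dropped)
}
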