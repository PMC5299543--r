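#' Individual participant data tables
#'
#' An `ipd_table` is a validated data frame of patient-level records from a
#' set of randomised trials, the exchange format used throughout the package.
#' One row per patient, with canonical columns:
#'
#' \describe{
#'   \item{`trial_id`}{trial label (any atomic type, stored as character).}
#'   \item{`patient_id`}{patient label, unique within trial.}
#'   \item{`z`}{treatment arm, 0 = control, 1 = experimental.}
#'   \item{`x`}{the patient-level covariate of interest (binary 0/1 or
#'     continuous, e.g. age in years).}
#'   \item{`time`}{follow-up time, strictly positive.}
#'   \item{`event`}{1 = event observed, 0 = censored.}
#' }
#'
#' Any further columns are carried along as extra adjustment covariates.
#' Validation enforces that every trial has at least two patients and both
#' treatment arms represented, that `time > 0`, that `z` and `event` are 0/1,
#' that `patient_id` is unique within `trial_id`, and that none of the
#' canonical columns is missing a value (the models here have no
#' missing-data mechanism; impute or drop before import).
#'
#' @param data a data frame holding the columns above.
#' @param extra_covariates character vector naming additional adjustment
#'   columns to carry (default: every non-canonical column of `data`).
#'
#' @return An object of class `ipd_table` (a data frame).
#' @export
#' @examples
#' d <- data.frame(trial_id = rep(1:2, each = 3), patient_id = rep(1:3, 2),
#'                 z = c(0, 1, 1, 0, 0, 1), x = c(0, 1, 0, 1, 1, 0),
#'                 time = c(1, 2, 3, 1.5, 2.5, 0.5), event = c(1, 0, 1, 1, 0, 1))
#' ipd <- ipd_table(d)
ipd_table <- function(data, extra_covariates = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  missing_cols <- setdiff(.ipd_canonical, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(extra_covariates)) {
    extra_covariates <- setdiff(names(data), .ipd_canonical)
  }
  data <- data[, c(.ipd_canonical, extra_covariates), drop = FALSE]
  data$trial_id <- as.character(data$trial_id)
  data$patient_id <- as.character(data$patient_id)
  for (col in c("z", "x", "time", "event")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  validate_ipd(data, extra_covariates)
  structure(data, class = c("ipd_table", "data.frame"),
            extra_covariates = extra_covariates)
}

.ipd_canonical <- c("trial_id", "patient_id", "z", "x", "time", "event")

# row labels used in validation messages: trial/patient if available, else index
.row_label <- function(data, idx) {
  paste0(data$trial_id[idx], "/", data$patient_id[idx])
}

validate_ipd <- function(data, extra_covariates = character(0)) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop("invalid IPD: ", what, " in row(s) ",
           paste(head(.row_label(data, idx), 10L), collapse = ", "),
           if (length(idx) > 10L) sprintf(" (and %d more)", length(idx) - 10L),
           call. = FALSE)
    }
  }
  for (col in c("z", "x", "time", "event")) {
    bad(is.na(data[[col]]), paste0("missing or unparseable '", col, "'"))
  }
  for (col in extra_covariates) {
    bad(is.na(data[[col]]), paste0("missing value in covariate '", col, "'"))
  }
  bad(!data$z %in% c(0, 1), "treatment indicator z not in {0,1}")
  bad(!data$event %in% c(0, 1), "event indicator not in {0,1}")
  bad(data$time <= 0, "non-positive follow-up time")
  dup <- duplicated(data[, c("trial_id", "patient_id")])
  bad(dup, "duplicated patient_id within trial_id")
  by_trial <- split(seq_len(nrow(data)), data$trial_id)
  for (tid in names(by_trial)) {
    idx <- by_trial[[tid]]
    if (length(idx) < 2L) {
      stop("invalid IPD: trial '", tid, "' has fewer than 2 patients",
           call. = FALSE)
    }
    if (length(unique(data$z[idx])) < 2L) {
      stop("invalid IPD: trial '", tid, "' lacks one of the treatment arms",
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Read an IPD table from delimited text
#'
#' Reads a comma-separated file (header row, UTF-8) into a validated
#' [ipd_table()].  Column names in the file can be mapped onto the canonical
#' names through `column_map`; any unmapped surplus columns named in
#' `extra_covariates` are carried as additional adjustment covariates.
#' Rows whose mapped fields do not parse as numbers are reported in the
#' error, never silently dropped.
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping canonical names to the
#'   names used in the file, e.g. `c(z = "treat", x = "age")`.  Canonical
#'   names absent from the map are looked up verbatim.
#' @param extra_covariates names (in the file) of further covariate columns
#'   to carry along.
#'
#' @return An [ipd_table()].
#' @seealso [write_ipd()]
#' @export
read_ipd <- function(path, column_map = NULL, extra_covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  name_for <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      column_map[[canon]]
    } else {
      canon
    }
  }
  out <- list()
  for (canon in .ipd_canonical) {
    src <- name_for(canon)
    if (!src %in% names(raw)) {
      stop("column '", src, "' (mapped to '", canon, "') not found in ", path,
           call. = FALSE)
    }
    out[[canon]] <- raw[[src]]
  }
  if (is.null(extra_covariates)) {
    used <- vapply(.ipd_canonical, name_for, character(1))
    extra_covariates <- setdiff(names(raw), used)
  }
  for (col in extra_covariates) {
    if (!col %in% names(raw)) {
      stop("extra covariate column '", col, "' not found in ", path,
           call. = FALSE)
    }
    out[[col]] <- as.numeric(raw[[col]])
  }
  out <- as.data.frame(out, check.names = FALSE)
  for (col in c("z", "x", "time", "event")) {
    suppressWarnings(out[[col]] <- as.numeric(out[[col]]))
  }
  ipd_table(out, extra_covariates = extra_covariates)
}

#' Write an IPD table as delimited text
#'
#' Writes CSV with a header, canonical column order (`trial_id, patient_id,
#' z, x, time, event`, extras last) and full numeric precision, so that
#' `read_ipd(write_ipd(x))` reproduces `x` field for field.
#'
#' @param table an [ipd_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(table, path) {
  stopifnot(inherits(table, "ipd_table"))
  df <- as.data.frame(table)
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Per-trial summaries and within-trial centring
#'
#' Centres the patient-level covariate `x` about its empirical mean within
#' each trial, appending a column `x_centred`, and returns per-trial
#' summaries.  Within-trial centring is what separates the within-trial
#' interaction (patient-level contrasts) from the across-trial association
#' of trial mean covariate with trial treatment effect; the original `x`
#' is retained unchanged.
#'
#' A trial in which `x` is constant contributes no within-trial interaction
#' information; it is flagged with a warning in the summary (`constant_x`),
#' not treated as an error.
#'
#' @param table an [ipd_table()].
#' @return A list with elements:
#'   \describe{
#'     \item{`table`}{the input with an added `x_centred` column and an added
#'       `x_bar` column holding the trial mean (handy for design building).}
#'     \item{`trials`}{a data frame with one row per trial: `trial_id`,
#'       `n`, `x_bar`, `constant_x`.}
#'   }
#' @export
centre_covariate <- function(table) {
  stopifnot(inherits(table, "ipd_table"))
  xbar <- tapply(table$x, table$trial_id, mean)
  n_j <- tapply(table$x, table$trial_id, length)
  const <- tapply(table$x, table$trial_id, function(v) var(v) == 0)
  trials <- data.frame(
    trial_id = names(xbar),
    n = as.integer(n_j[names(xbar)]),
    x_bar = as.numeric(xbar),
    constant_x = as.logical(const[names(xbar)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(trials$constant_x)) {
    warning("covariate is constant in trial(s) ",
            paste(trials$trial_id[trials$constant_x], collapse = ", "),
            ": no within-trial interaction information there", call. = FALSE)
  }
  tab <- as.data.frame(table)
  tab$x_bar <- as.numeric(xbar[tab$trial_id])
  tab$x_centred <- tab$x - tab$x_bar
  attrs <- attributes(table)
  out <- structure(tab, class = c("ipd_table", "data.frame"),
                   extra_covariates = attrs$extra_covariates)
  list(table = out, trials = trials)
}

#' @export
print.ipd_table <- function(x, ...) {
  nt <- length(unique(x$trial_id))
  cat(sprintf("IPD table: %d patients in %d trial(s), %d event(s)\n",
              nrow(x), nt, sum(x$event)))
  extras <- attr(x, "extra_covariates")
  if (length(extras) > 0L) {
    cat("extra covariates:", paste(extras, collapse = ", "), "\n")
  }
  print(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
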