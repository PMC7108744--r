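#' Session CSV input/output
#'
#' One row per trial with columns `subject_id`, `opponent`, `framing`,
#' `repetition`, `trial`, `a_self`, `a_op`, `reward` (actions coded 0/1,
#' header mandatory).  Reading validates the schema and rejects duplicate
#' (subject, condition, trial) keys; write-then-read round-trips exactly.
#'
#' @param path File path.
#' @param sessions Session data frame.
#' @param n_trials Expected trials per session.
#' @return `read_sessions()` returns the validated data frame;
#'   `write_sessions()` invisibly returns `path`.
#' @export
read_sessions <- function(path, n_trials = 60) {
  x <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    subject_id = "character", opponent = "character", framing = "character",
    repetition = "character"))
  key <- interaction(x$subject_id, x$opponent, x$framing, x$repetition, x$trial)
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), ][1, ]
    stop(sprintf("duplicate trial key at %s/%s/%s/rep%s trial %d",
                 d$subject_id, d$opponent, d$framing, d$repetition, d$trial))
  }
  validate_sessions(x, n_trials = n_trials)
  x
}

#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  validate_sessions(sessions, n_trials = length(unique(sessions$trial)))
  write.csv(sessions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort metadata CSV input/output
#'
#' @param cohort Data frame with at least `subject_id`, `group`,
#'   `symptom_social`, `symptom_stereotyped`.
#' @param path File path.
#' @return The cohort data frame (read) or `path`, invisibly (write).
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(subject_id = "character"))
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evidence table TSV input/output
#'
#' @param evidence Evidence table from [fit_cohort()].
#' @param path File path.
#' @return The evidence table (read) or `path`, invisibly (write).
#' @export
read_evidence <- function(path) {
  x <- read.csv(path, sep = "\t", stringsAsFactors = FALSE, colClasses = c(
    subject_id = "character", repetition = "character"))
  validate_evidence(x)
  x
}

#' @rdname read_evidence
#' @export
write_evidence <- function(evidence, path) {
  write.table(evidence, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ground-truth strategy labels JSON input/output
#'
#' @param truth Per-session true strategies (from [generate_cohort()]).
#' @param path File path.
#' @return The truth data frame (read) or `path`, invisibly (write).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                stringsAsFactors = FALSE)
}

#' Run configuration JSON
#'
#' A serializable run configuration: master seed, cohort settings and
#' inference settings.  Unknown keys are rejected so that typos fail loudly.
#'
#' @param seed Master seed.
#' @param n_per_group Participants per group.
#' @param n_restarts,maxit Inference settings (see [inference_config()]);
#'   the cohort-scale default (2 restarts) trades a little MAP polish for
#'   a tractable 6144-fit sweep and changes model posteriors negligibly.
#' @param n_permutations Permutations for the classification chance test.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_per_group = 24, n_restarts = 2,
                       maxit = 50, n_permutations = 1000) {
  structure(list(seed = seed, n_per_group = n_per_group,
                 n_restarts = n_restarts, maxit = maxit,
                 n_permutations = n_permutations), class = "run_config")
}

#' @rdname run_config
#' @param path File path.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
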