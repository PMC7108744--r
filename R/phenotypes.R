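#' Repertoire flexibility between two conditions
#'
#' Posterior probability that a participant used different adaptation
#' strategies in two conditions: `1 - sum_m p(m | a1) p(m | a2)`.
#'
#' @param posterior_1,posterior_2 Model posteriors (same model set) as
#'   returned by [model_posterior()].
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' u <- rep(1 / 8, 8)
#' flexibility(u, u)  # 0.875
flexibility <- function(posterior_1, posterior_2) {
  if (length(posterior_1) != length(posterior_2))
    stop("posteriors are over different model sets")
  n1 <- names(posterior_1); n2 <- names(posterior_2)
  if (!is.null(n1) && !is.null(n2)) {
    if (!setequal(n1, n2)) stop("posteriors are over different model sets")
    posterior_2 <- posterior_2[n1]
  }
  1 - sum(posterior_1 * posterior_2)
}

#' ToM sophistication of a model posterior
#'
#' Expected recursion depth `sum_k k * p(m = k-ToM | a)` over the k-ToM
#' models (k = 0..3).  By default the posterior over the full eight-model
#' set is used without renormalizing over the ToM subset, so mass on
#' non-ToM models contributes depth 0; `renormalize = TRUE` conditions on
#' the ToM subset instead (sensitivity variant).
#'
#' @param posterior Named model posterior over the eight models.
#' @param renormalize Condition on the k-ToM subset first.
#' @return A number in `[0, 3]`.
#' @export
tom_sophistication <- function(posterior, renormalize = FALSE) {
  tom <- paste0(0:3, "-ToM")
  if (is.null(names(posterior))) stop("posterior must be named by model")
  if (!all(tom %in% names(posterior))) stop("posterior lacks k-ToM entries")
  p <- posterior[tom]
  if (renormalize) {
    if (sum(p) <= 0) return(0)
    p <- p / sum(p)
  }
  sum((0:3) * p)
}

#' Per-participant computational phenotype profile
#'
#' Flexibility across framings is the mean of [flexibility()] over the 8
#' matched (opponent, repetition) session pairs; flexibility across
#' repetitions the mean over the 8 matched (opponent, framing) pairs.  ToM
#' sophistication per framing is the mean of [tom_sophistication()] over
#' that framing's 8 sessions.  The deltas are `f_framing - f_repetitions`
#' and `k_social - k_nonsocial`.
#'
#' @param evidence Evidence table rows for one subject (16 complete
#'   sessions x 8 models).
#' @param include_rb Include the pseudo-random opponent's sessions in the
#'   averages (default TRUE).
#' @param renormalize Passed to [tom_sophistication()].
#' @return A one-row data frame with `subject_id`, `f_framing`,
#'   `f_repetitions`, `k_social`, `k_nonsocial`, `delta_f`, `delta_k`.
#' @export
participant_profile <- function(evidence, include_rb = TRUE,
                                renormalize = FALSE) {
  subject <- unique(evidence$subject_id)
  if (length(subject) != 1) stop("evidence must belong to a single subject")
  opponents <- if (include_rb) OPPONENT_LEVELS else setdiff(OPPONENT_LEVELS, "RB")
  need <- expand.grid(opponent = opponents, framing = FRAMING_LEVELS,
                      repetition = REPETITION_LEVELS, stringsAsFactors = FALSE)
  post <- list()
  for (i in seq_len(nrow(need))) {
    sel <- evidence$opponent == need$opponent[i] &
      evidence$framing == need$framing[i] &
      evidence$repetition == need$repetition[i]
    if (sum(sel) != length(TOMREP_MODELS))
      stop(sprintf("subject %s: missing or incomplete session %s/%s/rep%s",
                   subject, need$opponent[i], need$framing[i], need$repetition[i]))
    post[[paste(need$opponent[i], need$framing[i], need$repetition[i], sep = "|")]] <-
      model_posterior(evidence[sel, ])
  }
  pget <- function(o, f, r) post[[paste(o, f, r, sep = "|")]]
  f_framing <- mean(unlist(lapply(opponents, function(o)
    lapply(REPETITION_LEVELS, function(r)
      flexibility(pget(o, "social", r), pget(o, "non-social", r))))))
  f_repetitions <- mean(unlist(lapply(opponents, function(o)
    lapply(FRAMING_LEVELS, function(f)
      flexibility(pget(o, f, "1"), pget(o, f, "2"))))))
  k_by_framing <- vapply(FRAMING_LEVELS, function(f)
    mean(unlist(lapply(opponents, function(o)
      lapply(REPETITION_LEVELS, function(r)
        tom_sophistication(pget(o, f, r), renormalize))))), numeric(1))
  data.frame(subject_id = subject, f_framing = f_framing,
             f_repetitions = f_repetitions,
             k_social = unname(k_by_framing["social"]),
             k_nonsocial = unname(k_by_framing["non-social"]),
             delta_f = f_framing - f_repetitions,
             delta_k = unname(k_by_framing["social"] - k_by_framing["non-social"]),
             stringsAsFactors = FALSE)
}

#' Phenotype table for a whole cohort
#'
#' @param evidence Full evidence table.
#' @param cohort Optional cohort metadata (`subject_id`, `group`, symptom
#'   scores) merged onto the result.
#' @param ... Passed to [participant_profile()].
#' @return One row per subject.
#' @export
phenotype_table <- function(evidence, cohort = NULL, ...) {
  profs <- do.call(rbind, lapply(split(evidence, evidence$subject_id),
                                 participant_profile, ...))
  rownames(profs) <- NULL
  if (!is.null(cohort)) profs <- merge(cohort, profs, by = "subject_id")
  profs
}
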