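#' Round-robin tournament between two agents
#'
#' Plays `n_games` independent games and returns the focal (first) agent's
#' per-game net correct rate.  Seeds are derived deterministically from
#' `seed`.
#'
#' @param agent_a Focal agent (records taken from its perspective).
#' @param agent_b Opponent agent.
#' @param n_games Number of games.
#' @param n_trials Trials per game.
#' @param seed Master seed.
#' @return Numeric vector of length `n_games`.
#' @export
tournament <- function(agent_a, agent_b, n_games = 200, n_trials = 60,
                       seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_games)
  vapply(seeds, function(s)
    net_correct_rate(play_game(agent_a, agent_b, n_trials = n_trials, seed = s)),
    numeric(1))
}

#' Calibrated tournament agent
#'
#' Agents at the package's calibrated operating point (see
#' [default_strategy_params()]): near-deterministic choices so that
#' predictive skill, not choice noise, determines earnings.  At this
#' operating point the characteristic orderings hold: mentalizing beats
#' frequency tracking, deeper mentalizing beats shallower, and influence
#' learning beats the frequency tracker but loses to mentalizers.
#'
#' @param name One of [repertoire_models()].
#' @param role `"seeker"` or `"hider"`.
#' @return An agent object.
#' @export
tournament_agent <- function(name, role) {
  agent_from_strategy(name, role, params = default_strategy_params())
}

#' Run the full phenotyping pipeline on a synthetic cohort
#'
#' Generates a cohort, fits the eight-model repertoire to every session,
#' derives the computational phenotypes, classifies group by leave-one-out
#' logistic regression (performance features alone and augmented with the
#' phenotypes), and regresses the social symptom score on the phenotypes
#' within the AS-like group.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A list with `cohort` (generation output), `evidence`,
#'   `profiles`, `classification_performance`,
#'   `classification_augmented`, `regression_social`,
#'   `regression_stereotyped`, and the `config`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("generating synthetic cohort (", 2 * config$n_per_group, " participants)")
  spec <- cohort_spec(n_per_group = config$n_per_group, seed = config$seed)
  cohort <- generate_cohort(spec)
  say("fitting ", length(TOMREP_MODELS), " models to ",
      nrow(session_keys(cohort$sessions)), " sessions")
  infc <- inference_config(n_restarts = config$n_restarts,
                           maxit = config$maxit, seed = config$seed)
  evidence <- fit_cohort(cohort$sessions, config = infc, verbose = verbose)
  validate_evidence(evidence)
  say("deriving phenotypes")
  profiles <- phenotype_table(evidence, cohort = cohort$participants)
  say("classifying group (leave-one-out)")
  feat_perf <- assemble_features(cohort$sessions, cohort$participants)
  feat_aug <- assemble_features(cohort$sessions, cohort$participants,
                                profiles = profiles, include_phenotypes = TRUE)
  cls_perf <- loo_classify(feat_perf, n_permutations = config$n_permutations,
                           seed = config$seed)
  cls_aug <- loo_classify(feat_aug, n_permutations = config$n_permutations,
                          seed = config$seed)
  say("symptom regressions (AS-like group)")
  as_prof <- profiles[profiles$group == "AS", ]
  reg_soc <- symptom_regression(as_prof, "symptom_social")
  reg_ster <- symptom_regression(as_prof, "symptom_stereotyped")
  list(cohort = cohort, evidence = evidence, profiles = profiles,
       classification_performance = cls_perf,
       classification_augmented = cls_aug,
       regression_social = reg_soc, regression_stereotyped = reg_ster,
       config = config)
}

#' Human-readable summary of a pipeline run
#'
#' @param result Output of [run_pipeline()].
#' @return Invisibly, a character vector of report lines (also printed).
#' @export
pipeline_report <- function(result) {
  pr <- result$profiles
  gm <- function(col) tapply(pr[[col]], pr$group, mean)
  lines <- c(
    "== Synthetic cohort phenotyping report ==",
    sprintf("participants: %d AS-like, %d NT-like",
            sum(pr$group == "AS"), sum(pr$group == "NT")),
    "",
    "group means (AS / NT):",
    sprintf("  f_framing      %.3f / %.3f", gm("f_framing")["AS"], gm("f_framing")["NT"]),
    sprintf("  f_repetitions  %.3f / %.3f", gm("f_repetitions")["AS"], gm("f_repetitions")["NT"]),
    sprintf("  k_social       %.3f / %.3f", gm("k_social")["AS"], gm("k_social")["NT"]),
    sprintf("  k_nonsocial    %.3f / %.3f", gm("k_nonsocial")["AS"], gm("k_nonsocial")["NT"]),
    sprintf("  delta_f        %.3f / %.3f", gm("delta_f")["AS"], gm("delta_f")["NT"]),
    sprintf("  delta_k        %.3f / %.3f", gm("delta_k")["AS"], gm("delta_k")["NT"]),
    "",
    sprintf("LOO accuracy, performance features: %.3f (p = %.4g)",
            result$classification_performance$loo_accuracy,
            result$classification_performance$p_value),
    sprintf("LOO accuracy, + phenotypes:         %.3f (p = %.4g)",
            result$classification_augmented$loo_accuracy,
            result$classification_augmented$p_value),
    "",
    sprintf("symptom regression (AS-like, social): R^2 = %.3f, F(%d,%d) = %.2f, p = %.4g",
            result$regression_social$r_squared, result$regression_social$df[1],
            result$regression_social$df[2], result$regression_social$f_statistic,
            result$regression_social$p_value),
    sprintf("  delta_k slope %.3f, delta_f slope %.3f",
            result$regression_social$univariate$delta_k$slope,
            result$regression_social$univariate$delta_f$slope),
    sprintf("symptom regression (AS-like, stereotyped): R^2 = %.3f, p = %.4g",
            result$regression_stereotyped$r_squared,
            result$regression_stereotyped$p_value))
  cat(lines, sep = "\n")
  invisible(lines)
}
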