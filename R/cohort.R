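#' Group generative profile
#'
#' A profile holds one strategy repertoire per framing (a probability
#' simplex over the eight models) and two switch rates: the probability of
#' re-drawing the strategy between the two repetitions of a condition, and
#' between the two framings of an opponent condition.  The framing switch
#' rate couples strategy draws across framings; without it a group with
#' identical per-framing repertoires would mechanically show large
#' cross-framing flexibility from independent draws.
#'
#' @param repertoire_social,repertoire_nonsocial Named nonnegative weights
#'   over (a subset of) [repertoire_models()]; normalized internally.
#' @param switch_rate_repetition,switch_rate_framing Probabilities in
#'   `[0, 1]`.
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(repertoire_social, repertoire_nonsocial,
                           switch_rate_repetition, switch_rate_framing) {
  norm_rep <- function(w) {
    if (is.null(names(w)) || !all(names(w) %in% TOMREP_MODELS))
      stop("repertoire weights must be named by model")
    if (any(w < 0) || sum(w) <= 0) stop("repertoire weights must be nonnegative")
    full <- setNames(rep(0, length(TOMREP_MODELS)), TOMREP_MODELS)
    full[names(w)] <- w
    full / sum(full)
  }
  stopifnot(switch_rate_repetition >= 0, switch_rate_repetition <= 1,
            switch_rate_framing >= 0, switch_rate_framing <= 1)
  structure(list(repertoire_social = norm_rep(repertoire_social),
                 repertoire_nonsocial = norm_rep(repertoire_nonsocial),
                 switch_rate_repetition = switch_rate_repetition,
                 switch_rate_framing = switch_rate_framing),
            class = "cohort_profile")
}

#' Default group profiles
#'
#' The AS-like profile is dominated by influence learning in both framings
#' with low switch rates; the NT-like profile uses simple non-mentalizing
#' strategies in the non-social framing, mentalizing (1-/2-ToM) strategies
#' in the social framing, and switches more freely.
#'
#' @return A `cohort_profile`.
#' @export
profile_as_like <- function() {
  rep_both <- c("WSLS" = 0.05, "RL" = 0.05, "0-ToM" = 0.10, "Inf" = 0.65,
                "1-ToM" = 0.15)
  cohort_profile(rep_both, rep_both,
                 switch_rate_repetition = 0.2, switch_rate_framing = 0.2)
}

#' @rdname profile_as_like
#' @export
profile_nt_like <- function() {
  cohort_profile(
    repertoire_social = c("0-ToM" = 0.10, "Inf" = 0.10, "1-ToM" = 0.50,
                          "2-ToM" = 0.30),
    repertoire_nonsocial = c("WSLS" = 0.25, "RL" = 0.30, "0-ToM" = 0.25,
                             "Inf" = 0.20),
    switch_rate_repetition = 0.5, switch_rate_framing = 0.9)
}

#' Synthetic cohort specification
#'
#' @param n_per_group Participants per group (>= 2).
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param as_profile,nt_profile Group [cohort_profile()]s.
#' @param strategy_params Generative parameters for participant agents
#'   (see [default_strategy_params()]).
#' @param opponent_params `sigma` (k >= 1), `sigma0` (frequency tracker)
#'   and `beta` of the artificial opponents, calibrated to be decisive.
#' @param symptom_model Linear model mapping the true phenotype deltas to
#'   the social symptom subscore: `intercept + coef_delta_k * delta_k +
#'   coef_delta_f * delta_f + N(0, noise_sd)`, truncated at 0; the
#'   stereotyped subscore is independent noise.
#' @param n_trials Trials per game.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 24, seed = 1,
                        as_profile = profile_as_like(),
                        nt_profile = profile_nt_like(),
                        strategy_params = default_strategy_params(),
                        opponent_params = list(sigma = 0.1, sigma0 = 1,
                                               beta = 0.15),
                        symptom_model = list(intercept = 10, coef_delta_k = -3,
                                             coef_delta_f = -5, noise_sd = 1.5,
                                             stereotyped_mean = 5,
                                             stereotyped_sd = 2),
                        n_trials = 60) {
  stopifnot(n_per_group >= 2, symptom_model$noise_sd >= 0)
  structure(list(n_per_group = n_per_group, seed = seed,
                 as_profile = as_profile, nt_profile = nt_profile,
                 strategy_params = strategy_params,
                 opponent_params = opponent_params,
                 symptom_model = symptom_model, n_trials = n_trials),
            class = "cohort_spec")
}

strategy_depth <- function(m) {
  k <- match(m, paste0(0:3, "-ToM"))
  ifelse(is.na(k), 0, k - 1)
}

#' Draw one synthetic participant
#'
#' Draws a ground-truth strategy for each of the 16 conditions from the
#' group profile (coupled across framings and repetitions through the
#' switch rates), computes the participant's true phenotypes from those
#' labels, and draws symptom scores from the linear symptom model.  Uses
#' the current RNG stream.
#'
#' @param spec A [cohort_spec()].
#' @param group `"AS"` or `"NT"`.
#' @param subject_id Identifier.
#' @return A list with `subject_id`, `group`, `assignment` (16-row data
#'   frame of true strategies), true phenotypes, and symptom scores.
#' @export
draw_participant <- function(spec, group, subject_id = "S1") {
  group <- match.arg(group, c("AS", "NT"))
  prof <- if (group == "AS") spec$as_profile else spec$nt_profile
  draw <- function(rep) sample(TOMREP_MODELS, 1, prob = rep)
  rows <- list()
  for (o in OPPONENT_LEVELS) {
    m_ns1 <- draw(prof$repertoire_nonsocial)
    m_ns2 <- if (runif(1) < prof$switch_rate_repetition)
      draw(prof$repertoire_nonsocial) else m_ns1
    m_s1 <- if (runif(1) < prof$switch_rate_framing)
      draw(prof$repertoire_social) else m_ns1
    m_s2 <- if (runif(1) < prof$switch_rate_repetition)
      draw(prof$repertoire_social) else m_s1
    rows[[o]] <- data.frame(
      opponent = o,
      framing = rep(FRAMING_LEVELS, each = 2),
      repetition = rep(REPETITION_LEVELS, 2),
      strategy = c(m_s1, m_s2, m_ns1, m_ns2),
      stringsAsFactors = FALSE)
  }
  assignment <- do.call(rbind, rows)
  rownames(assignment) <- NULL
  soc <- assignment[assignment$framing == "social", ]
  ns <- assignment[assignment$framing == "non-social", ]
  soc <- soc[order(soc$opponent, soc$repetition), ]
  ns <- ns[order(ns$opponent, ns$repetition), ]
  f_framing_true <- mean(soc$strategy != ns$strategy)
  f_rep_true <- mean(unlist(lapply(split(assignment,
    interaction(assignment$opponent, assignment$framing)),
    function(s) s$strategy[s$repetition == "1"] != s$strategy[s$repetition == "2"])))
  k_social_true <- mean(strategy_depth(soc$strategy))
  k_nonsocial_true <- mean(strategy_depth(ns$strategy))
  delta_k_true <- k_social_true - k_nonsocial_true
  delta_f_true <- f_framing_true - f_rep_true
  sm <- spec$symptom_model
  symptom_social <- max(0, round(sm$intercept + sm$coef_delta_k * delta_k_true +
                                   sm$coef_delta_f * delta_f_true +
                                   rnorm(1, 0, sm$noise_sd)))
  symptom_stereotyped <- max(0, round(rnorm(1, sm$stereotyped_mean,
                                            sm$stereotyped_sd)))
  list(subject_id = subject_id, group = group, assignment = assignment,
       f_framing_true = f_framing_true, f_repetitions_true = f_rep_true,
       k_social_true = k_social_true, k_nonsocial_true = k_nonsocial_true,
       delta_f_true = delta_f_true, delta_k_true = delta_k_true,
       symptom_social = symptom_social,
       symptom_stereotyped = symptom_stereotyped)
}

opponent_agent <- function(opponent, spec) {
  if (opponent == "RB") return(agent_rb(role = "hider"))
  k <- as.integer(substr(opponent, 1, 1))
  sg <- if (k == 0) spec$opponent_params$sigma0 else spec$opponent_params$sigma
  agent_tom(k, role = "hider", sigma = sg, beta = spec$opponent_params$beta)
}

#' Generate a full synthetic cohort
#'
#' For every participant, each of the 16 conditions (4 opponents x 2
#' framings x 2 repetitions) is played for `n_trials` trials: the
#' participant agent realizes the drawn ground-truth strategy (seeker), the
#' opponent is the condition's artificial agent (hider).  Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param verbose Print progress.
#' @return A list: `participants` (one row per subject: group, symptom
#'   scores, true phenotypes), `sessions` (stacked session records), and
#'   `truth` (per-session true strategy labels).
#' @export
generate_cohort <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- 2 * spec$n_per_group
  ids <- sprintf("S%02d", seq_len(n))
  groups <- rep(c("AS", "NT"), each = spec$n_per_group)
  participants <- list(); sessions <- list(); truth <- list()
  for (i in seq_len(n)) {
    pt <- draw_participant(spec, groups[i], ids[i])
    if (verbose) message("simulating ", ids[i], " (", groups[i], ")")
    for (j in seq_len(nrow(pt$assignment))) {
      a <- pt$assignment[j, ]
      seeker <- agent_from_strategy(a$strategy, role = "seeker",
                                    params = spec$strategy_params)
      hider <- opponent_agent(a$opponent, spec)
      seed_j <- sample.int(.Machine$integer.max, 1)
      sess <- play_game(seeker, hider, n_trials = spec$n_trials, seed = seed_j,
                        subject_id = ids[i], opponent = a$opponent,
                        framing = a$framing, repetition = a$repetition)
      sessions[[length(sessions) + 1L]] <- sess
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = ids[i], opponent = a$opponent, framing = a$framing,
        repetition = a$repetition, strategy = a$strategy, seed = seed_j,
        stringsAsFactors = FALSE)
    }
    participants[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i],
      symptom_social = pt$symptom_social,
      symptom_stereotyped = pt$symptom_stereotyped,
      f_framing_true = pt$f_framing_true,
      f_repetitions_true = pt$f_repetitions_true,
      k_social_true = pt$k_social_true,
      k_nonsocial_true = pt$k_nonsocial_true,
      delta_f_true = pt$delta_f_true, delta_k_true = pt$delta_k_true,
      stringsAsFactors = FALSE)
  }
  list(participants = do.call(rbind, participants),
       sessions = do.call(rbind, sessions),
       truth = do.call(rbind, truth))
}
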