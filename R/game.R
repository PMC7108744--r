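#' Competitive hide-and-seek payoff table
#'
#' Zero-sum payoffs for the repeated hide-and-seek game: the seeker earns 1
#' when both players pick the same option, the hider earns 1 when they
#' differ.  Payoffs are complementary (they sum to 1 in every cell).
#'
#' @param role `"seeker"` or `"hider"`.
#' @param a_self,a_op Binary actions (0/1) of the focal player and the
#'   opponent.
#' @return Payoff in `{0, 1}` for the focal player.
#' @export
#' @examples
#' payoff("seeker", 1, 1)  # seeker found the hider: 1
#' payoff("hider", 1, 1)   # hider was found: 0
payoff <- function(role, a_self, a_op) {
  role <- match.arg(role, c("seeker", "hider"))
  stopifnot(all(a_self %in% 0:1), all(a_op %in% 0:1))
  if (role == "seeker") as.numeric(a_self == a_op) else as.numeric(a_self != a_op)
}

role_sign <- function(role) {
  role <- match.arg(role, c("seeker", "hider"))
  if (role == "seeker") 1L else -1L
}

#' Expected payoff difference between the two options
#'
#' Under the competitive payoff table, the expected payoff difference between
#' choosing 1 and choosing 0 is `2 * p_op - 1` for the seeker and its
#' negative for the hider, where `p_op` is the predicted probability that
#' the opponent plays 1.
#'
#' @param p_op Probability in `[0, 1]` that the opponent plays 1.
#' @param role `"seeker"` or `"hider"`.
#' @return The expected value difference, in `[-1, 1]`.
#' @export
#' @examples
#' expected_value_difference(0.3, "hider")  # 0.4
expected_value_difference <- function(p_op, role) {
  if (any(!is.finite(p_op)) || any(p_op < 0) || any(p_op > 1))
    stop("p_op must lie in [0, 1]")
  role_sign(role) * (2 * p_op - 1)
}

#' Softmax decision policy
#'
#' All value-based agents share one probabilistic decision rule: action 1 is
#' chosen with probability `sigmoid((delta_v + bias) / beta)`.  `beta` is the
#' behavioural temperature (larger = noisier choices) and `bias` a constant
#' preference for option 1.
#'
#' @param beta Strictly positive temperature.
#' @param bias Additive offset on the value difference (any real).
#' @return An object of class `softmax_policy`.
#' @export
softmax_policy <- function(beta = 1, bias = 0) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be strictly positive")
  if (!is.finite(bias)) stop("bias must be finite")
  structure(list(beta = beta, bias = bias), class = "softmax_policy")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Choice probability under the softmax policy
#'
#' @param delta_v Expected payoff difference between options 1 and 0.
#' @param policy A [softmax_policy()].
#' @return Probability of choosing action 1, strictly inside (0, 1) for
#'   finite inputs.
#' @export
#' @examples
#' choice_probability(1, softmax_policy(beta = 1))  # ~0.731
choice_probability <- function(delta_v, policy = softmax_policy()) {
  stopifnot(inherits(policy, "softmax_policy"))
  sigmoid((delta_v + policy$bias) / policy$beta)
}

#' Net rate of correct answers
#'
#' `(n_c - n_i) / (n_c + n_i)` where `n_c` and `n_i` count rewarded and
#' unrewarded trials.  Equals 0 at chance-level performance and
#' `2 * (fraction correct) - 1` in general.
#'
#' @param session A session data frame with a `reward` column, or a numeric
#'   vector of per-trial rewards in `{0, 1}`.
#' @return A number in `[-1, 1]`.
#' @export
net_correct_rate <- function(session) {
  r <- if (is.data.frame(session)) session$reward else session
  if (length(r) == 0) stop("session has no trials")
  stopifnot(all(r %in% c(0, 1)))
  mean(r == 1) - mean(r == 0)
}

#' Assemble a session record
#'
#' One row per trial, recorded from the focal player's perspective.
#'
#' @param a_self,a_op Binary action sequences of equal length.
#' @param role Focal player's role (rewards follow the payoff table).
#' @param subject_id,opponent,framing,repetition Condition labels.
#' @return A `data.frame` with columns `subject_id`, `opponent`, `framing`,
#'   `repetition`, `trial`, `a_self`, `a_op`, `reward`.
#' @export
session_record <- function(a_self, a_op, role = "seeker", subject_id = "S1",
                           opponent = "RB", framing = "non-social",
                           repetition = "1") {
  stopifnot(length(a_self) == length(a_op))
  data.frame(
    subject_id = subject_id,
    opponent = match.arg(opponent, OPPONENT_LEVELS),
    framing = match.arg(framing, FRAMING_LEVELS),
    repetition = match.arg(as.character(repetition), REPETITION_LEVELS),
    trial = seq_along(a_self),
    a_self = as.integer(a_self),
    a_op = as.integer(a_op),
    reward = payoff(role, as.integer(a_self), as.integer(a_op)),
    stringsAsFactors = FALSE
  )
}

#' Validate a table of sessions
#'
#' Checks the session schema: binary actions, rewards consistent with the
#' seeker payoff table, condition labels from their fixed sets, and exactly
#' `n_trials` strictly increasing trial indices per session.
#'
#' @param sessions Session data frame (possibly many sessions stacked).
#' @param n_trials Required number of trials per session (default 60).
#' @param role Focal player's role used to check rewards.
#' @return Invisibly, `sessions`; stops with a descriptive error otherwise.
#' @export
validate_sessions <- function(sessions, n_trials = 60, role = "seeker") {
  need <- c("subject_id", "opponent", "framing", "repetition", "trial",
            "a_self", "a_op", "reward")
  miss <- setdiff(need, names(sessions))
  if (length(miss)) stop("missing session columns: ", paste(miss, collapse = ", "))
  if (!all(sessions$a_self %in% 0:1) || !all(sessions$a_op %in% 0:1))
    stop("actions must be coded 0/1")
  if (!all(sessions$opponent %in% OPPONENT_LEVELS))
    stop("unknown opponent labels: ",
         paste(setdiff(unique(sessions$opponent), OPPONENT_LEVELS), collapse = ", "))
  if (!all(sessions$framing %in% FRAMING_LEVELS)) stop("unknown framing labels")
  if (!all(as.character(sessions$repetition) %in% REPETITION_LEVELS))
    stop("unknown repetition labels")
  expected <- payoff(role, sessions$a_self, sessions$a_op)
  if (!isTRUE(all.equal(as.numeric(sessions$reward), expected)))
    stop("rewards inconsistent with the ", role, " payoff table")
  key <- interaction(sessions$subject_id, sessions$opponent, sessions$framing,
                     sessions$repetition, drop = TRUE)
  for (s in split(sessions, key)) {
    if (nrow(s) != n_trials)
      stop(sprintf("session %s/%s/%s/%s has %d trials (expected %d)",
                   s$subject_id[1], s$opponent[1], s$framing[1],
                   s$repetition[1], nrow(s), n_trials))
    if (any(diff(s$trial) <= 0)) stop("trial indices must be strictly increasing")
    if (anyDuplicated(s$trial)) stop("duplicate trial indices")
  }
  invisible(sessions)
}

#' Play one repeated game between two agents
#'
#' Simultaneous moves: on every trial both agents act, then both observe the
#' two actions (and their own payoff).  Identical seeds give bit-identical
#' records.
#'
#' @param agent_self,agent_op Agents built with the `agent_*` constructors;
#'   `agent_self` is the focal player whose perspective the record takes.
#' @param n_trials Number of trials (default 60).
#' @param seed Integer seed controlling all choice sampling.
#' @param ... Labels passed to [session_record()].
#' @return A session data frame (see [session_record()]).
#' @export
play_game <- function(agent_self, agent_op, n_trials = 60, seed = 1, ...) {
  stopifnot(n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  agent_self <- agent_reset(agent_self)
  agent_op <- agent_reset(agent_op)
  a1 <- integer(n_trials)
  a2 <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    a1[t] <- agent_act(agent_self)
    a2[t] <- agent_act(agent_op)
    r1 <- payoff(agent_self$role, a1[t], a2[t])
    r2 <- payoff(agent_op$role, a2[t], a1[t])
    agent_self <- tryCatch(
      agent_observe(agent_self, a_self = a1[t], a_op = a2[t], reward = r1),
      error = function(e) stop(sprintf("agent_self update failed at trial %d: %s",
                                       t, conditionMessage(e))))
    agent_op <- tryCatch(
      agent_observe(agent_op, a_self = a2[t], a_op = a1[t], reward = r2),
      error = function(e) stop(sprintf("agent_op update failed at trial %d: %s",
                                       t, conditionMessage(e))))
  }
  session_record(a1, a2, role = agent_self$role, ...)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
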