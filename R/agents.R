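#' @name agents
#' @title Adaptation-strategy agents
#'
#' @description
#' Constructors for the eight adaptation strategies plus the pseudo-random
#' opponent.  Every agent exposes the same contract: [agent_reset()] returns
#' a fresh-state copy, [agent_act()] samples an action from the shared
#' softmax policy applied to the agent's current value difference, and
#' [agent_observe()] updates the internal state after both actions are
#' revealed.
#'
#' * `agent_rb()`: predetermined pseudo-random schedule with a 65% bias for
#'   one option (no learning, ignores the softmax policy).
#' * `agent_bn()`: biased Nash — value difference fixed at 0, bias only.
#' * `agent_wsls()`: win-stay/lose-switch on signed rewards.
#' * `agent_rl()`: Rescorla-Wagner reinforcement learning.
#' * `agent_influence()`: frequency tracking plus a correction for how one's
#'   own actions steer the opponent.
#' * `agent_tom()`: recursive k-ToM meta-Bayesian learner (k = 0..3).
#'
#' @param role `"seeker"` or `"hider"`.
#' @param beta Behavioural temperature (> 0).
#' @param bias Additive preference for option 1.
NULL

new_agent <- function(class, name, role, beta = 1, bias = 0, ...) {
  structure(
    list(name = name, role = match.arg(role, c("seeker", "hider")),
         policy = softmax_policy(beta, bias), ...),
    class = c(class, "tomrep_agent"))
}

#' @rdname agents
#' @param bias_level Fraction of trials assigned to the preferred option.
#' @param n_trials Schedule length.
#' @param preferred Preferred option (0/1); drawn at reset when `NULL`.
#' @export
agent_rb <- function(role = "hider", bias_level = 0.65, n_trials = 60,
                     preferred = NULL) {
  stopifnot(bias_level >= 0, bias_level <= 1)
  new_agent("rb_agent", "RB", role, bias_level = bias_level,
            n_trials = n_trials, preferred = preferred, schedule = NULL, t = 0L)
}

#' @rdname agents
#' @export
agent_bn <- function(role = "seeker", bias = 0) {
  new_agent("bn_agent", "BN", role, beta = 1, bias = bias)
}

#' @rdname agents
#' @export
agent_wsls <- function(role = "seeker", beta = 1, bias = 0) {
  new_agent("wsls_agent", "WSLS", role, beta = beta, bias = bias,
            state = wsls_state())
}

#' @rdname agents
#' @param alpha Learning rate in (0, 1].
#' @export
agent_rl <- function(role = "seeker", alpha = 0.7, beta = 1, bias = 0) {
  new_agent("rl_agent", "RL", role, beta = beta, bias = bias,
            state = rl_state(alpha = alpha))
}

#' @rdname agents
#' @param eta Prediction-error weight in `[0, 1]`.
#' @param influence_weight Weight of the influence adjustment term.
#' @export
agent_influence <- function(role = "seeker", eta = 0.6, influence_weight = 0.3,
                            beta = 1, bias = 0) {
  new_agent("influence_agent", "Inf", role, beta = beta, bias = bias,
            state = influence_state(eta = eta, influence_weight = influence_weight,
                                    beta_inf = beta))
}

#' @rdname agents
#' @param k Sophistication level (0 to 3).
#' @param sigma Prior volatility of the opponent's hidden states (> 0).
#' @export
agent_tom <- function(k, role = "seeker", sigma = 1, beta = 1, bias = 0) {
  stopifnot(k %in% 0:3, sigma > 0)
  name <- paste0(k, "-ToM")
  new_agent("tom_agent", name, role, beta = beta, bias = bias,
            k = as.integer(k), sigma = sigma, ptr = NULL)
}

#' Build an agent from a repertoire strategy name
#'
#' @param name One of [repertoire_models()].
#' @param role Agent role.
#' @param params Named list overriding the default generative parameters
#'   (`beta`, `bias`, `sigma`, `alpha`, `eta`, `influence_weight`).
#' @return An agent object.
#' @export
agent_from_strategy <- function(name, role = "seeker", params = list()) {
  p <- utils::modifyList(default_strategy_params(), params)
  switch(match.arg(name, TOMREP_MODELS),
    "BN" = agent_bn(role, bias = p$bias),
    "WSLS" = agent_wsls(role, beta = p$beta, bias = p$bias),
    "RL" = agent_rl(role, alpha = p$alpha, beta = p$beta, bias = p$bias),
    "0-ToM" = agent_tom(0, role, sigma = p$sigma0, beta = p$beta, bias = p$bias),
    "Inf" = agent_influence(role, eta = p$eta,
                            influence_weight = p$influence_weight,
                            beta = p$beta, bias = p$bias),
    "1-ToM" = agent_tom(1, role, sigma = p$sigma, beta = p$beta, bias = p$bias),
    "2-ToM" = agent_tom(2, role, sigma = p$sigma, beta = p$beta, bias = p$bias),
    "3-ToM" = agent_tom(3, role, sigma = p$sigma, beta = p$beta, bias = p$bias))
}

#' Build an agent from a configuration list
#'
#' Accepts the agent block of a JSON run configuration: `type` (a model
#' name or `"RB"`), optional `role`, and the parameters the type uses
#' (`k`, `sigma`, `sigma0`, `beta`, `bias`, `eta`, `influence_weight`,
#' `alpha`, `bias_level`, `preferred`).  Unknown keys are rejected.
#'
#' @param config Named list (e.g. from `jsonlite::read_json`).
#' @return An agent object.
#' @export
agent_from_config <- function(config) {
  known <- c("type", "role", "k", "sigma", "sigma0", "beta", "bias", "eta",
             "influence_weight", "alpha", "bias_level", "preferred")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown agent configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$type)) stop("agent configuration needs a 'type'")
  role <- if (is.null(config$role)) "seeker" else config$role
  if (identical(config$type, "RB")) {
    args <- config[intersect(names(config), c("bias_level", "preferred"))]
    return(do.call(agent_rb, c(list(role = role), args)))
  }
  type <- if (!is.null(config$k)) paste0(config$k, "-ToM") else config$type
  pars <- config[intersect(names(config),
                           c("sigma", "sigma0", "beta", "bias", "eta",
                             "influence_weight", "alpha"))]
  agent_from_strategy(type, role, params = pars)
}

#' Default generative parameters for simulated agents
#'
#' Chosen so the eight models are distinguishable from 60-trial choice
#' sequences: near-deterministic choices (`beta = 0.15`, so an agent's
#' actions carry information about its strategy rather than being coin
#' flips), slow assumed parameter drift for the mentalizing learners
#' (`sigma = 0.1`), unit volatility on the choice log-odds for the
#' frequency tracker (`sigma0 = 1`), and an influence learner whose
#' adjustment term dominates its prediction error (`eta = 0.25`,
#' `influence_weight = 0.6`; at high `eta` influence learning degenerates
#' into copy-the-opponent's-last-action, which is exactly win-stay/
#' lose-switch under this payoff).
#'
#' @return Named list of parameter defaults.
#' @export
default_strategy_params <- function() {
  list(beta = 0.15, bias = 0, sigma = 0.1, sigma0 = 1, alpha = 0.7,
       eta = 0.25, influence_weight = 0.6)
}

# ---------------------------------------------------------------------------
# learner state containers + update rules (the readable reference
# implementations; the C++ likelihood path mirrors them and is cross-checked
# in the tests)
# ---------------------------------------------------------------------------

#' 0-ToM belief state and update
#'
#' A 0-ToM learner tracks the opponent's choice tendency as a Gaussian
#' belief over the log-odds `x` of playing 1, assumed to drift with
#' volatility `volatility` between trials.  The update is variance first:
#' `sigma2' = 1 / (1 / (sigma2 + volatility) + s(mu) (1 - s(mu)))`, then
#' `mu' = mu + sigma2' * (a_op - s(mu))` with `s` the logistic sigmoid.
#'
#' @param mu,sigma2 Posterior mean and variance of the log-odds.
#' @param volatility Prior volatility (> 0).
#' @return `tom0_state()` returns a state list; `tom0_update()` the updated
#'   state; `tom0_predict()` the posterior expectation of `s(x)` under the
#'   predictive belief `N(mu, sigma2 + volatility)`, approximated by the
#'   probit-style moment correction `s(mu / sqrt(1 + 3 V / pi^2))`.
#' @export
tom0_state <- function(mu = 0, sigma2 = 1, volatility = 1) {
  stopifnot(is.finite(mu), is.finite(sigma2), sigma2 > 0, volatility > 0)
  list(mu = mu, sigma2 = sigma2, volatility = volatility)
}

#' @rdname tom0_state
#' @param state A `tom0_state()`.
#' @param a_op Observed opponent action (0/1).
#' @export
tom0_update <- function(state, a_op) {
  stopifnot(a_op %in% 0:1)
  if (!all(is.finite(c(state$mu, state$sigma2)))) stop("non-finite 0-ToM state")
  s <- sigmoid(state$mu)
  sigma2_new <- 1 / (1 / (state$sigma2 + state$volatility) + s * (1 - s))
  mu_new <- state$mu + sigma2_new * (a_op - s)
  tom0_state(mu_new, sigma2_new, state$volatility)
}

#' @rdname tom0_state
#' @export
tom0_predict <- function(state) {
  v <- state$sigma2 + state$volatility
  sigmoid(state$mu / sqrt(1 + (3 / pi^2) * v))
}

#' Influence-learning state and update
#'
#' Tracks the opponent's probability of playing 1 and corrects the estimate
#' for how the learner's own action steers the opponent:
#' `p' = p + eta (a_op - p) + w p (1 - p) (1 - 2 a_self - beta_inf logit(p))`,
#' clipped to `[eps, 1 - eps]`.
#'
#' @param p_op Current estimate in (0, 1).
#' @param eta Prediction-error weight in `[0, 1]`.
#' @param influence_weight Weight `w` of the influence adjustment term.
#' @param beta_inf Temperature used inside the influence term.
#' @param eps Clipping constant.
#' @return A state list; `influence_update()` returns the updated state with
#'   the running clip count in `n_clipped`.
#' @export
influence_state <- function(p_op = 0.5, eta = 0.6, influence_weight = 0.3,
                            beta_inf = 1, eps = 1e-4) {
  stopifnot(p_op > 0, p_op < 1, eta >= 0, eta <= 1)
  list(p_op = p_op, eta = eta, influence_weight = influence_weight,
       beta_inf = beta_inf, eps = eps, n_clipped = 0L)
}

#' @rdname influence_state
#' @param state An `influence_state()`.
#' @param a_op,a_self Observed actions (0/1).
#' @export
influence_update <- function(state, a_op, a_self) {
  stopifnot(a_op %in% 0:1, a_self %in% 0:1)
  p <- state$p_op
  infl <- state$influence_weight * p * (1 - p) *
    (1 - 2 * a_self - state$beta_inf * log(p / (1 - p)))
  p_new <- p + state$eta * (a_op - p) + infl
  clipped <- p_new < state$eps || p_new > 1 - state$eps
  state$p_op <- min(1 - state$eps, max(state$eps, p_new))
  state$n_clipped <- state$n_clipped + as.integer(clipped)
  state
}

#' Reinforcement-learning and win-stay/lose-switch value states
#'
#' `rl_update()` moves the chosen option's value toward the reward by a
#' fraction `alpha` (the unchosen value is untouched).  `wsls_update()` sets
#' the chosen value to the signed reward (+1 win / -1 loss) and the
#' unchosen value to its negative, so the most probable next move is to
#' stay after a win and switch after a loss.
#'
#' @param values Numeric `c(v0, v1)` action values.
#' @param alpha Learning rate in (0, 1].
#' @return State lists; updates return the modified state.
#' @export
rl_state <- function(values = c(0, 0), alpha = 0.7) {
  stopifnot(alpha > 0, alpha <= 1, length(values) == 2)
  list(values = values, alpha = alpha)
}

#' @rdname rl_state
#' @param state State list.
#' @param a_self Chosen action (0/1).
#' @param reward Obtained payoff in `{0, 1}`.
#' @export
rl_update <- function(state, a_self, reward) {
  stopifnot(a_self %in% 0:1)
  i <- a_self + 1
  state$values[i] <- state$values[i] + state$alpha * (reward - state$values[i])
  state
}

#' @rdname rl_state
#' @export
wsls_state <- function(values = c(0, 0)) list(values = values)

#' @rdname rl_state
#' @export
wsls_update <- function(state, a_self, reward) {
  stopifnot(a_self %in% 0:1, reward %in% c(0, 1))
  r_signed <- if (reward == 1) 1 else -1
  i <- a_self + 1
  state$values[i] <- r_signed
  state$values[3 - i] <- -r_signed
  state
}

# ---------------------------------------------------------------------------
# agent contract
# ---------------------------------------------------------------------------

#' Agent contract: reset, predict, act, observe
#'
#' @param agent An agent object.
#' @param a_self,a_op Observed actions (0/1) from the agent's perspective.
#' @param reward The agent's payoff on the trial.
#' @return `agent_reset()` and `agent_observe()` return the (updated) agent;
#'   `agent_predict()` the predicted probability that the opponent plays 1
#'   (belief-based agents only); `agent_delta_v()` the current value
#'   difference; `agent_act()` a sampled binary action (uses the session
#'   RNG; the pseudo-random opponent returns its scheduled action).
#' @export
agent_reset <- function(agent) UseMethod("agent_reset")

#' @rdname agent_reset
#' @export
agent_predict <- function(agent) UseMethod("agent_predict")

#' @rdname agent_reset
#' @export
agent_delta_v <- function(agent) UseMethod("agent_delta_v")

#' @rdname agent_reset
#' @export
agent_observe <- function(agent, a_self, a_op, reward) UseMethod("agent_observe")

#' @rdname agent_reset
#' @export
agent_act <- function(agent) UseMethod("agent_act")

#' @export
agent_act.tomrep_agent <- function(agent) {
  p1 <- choice_probability(agent_delta_v(agent), agent$policy)
  as.integer(stats::runif(1) < p1)
}

#' @export
agent_delta_v.tomrep_agent <- function(agent) {
  expected_value_difference(agent_predict(agent), agent$role)
}

#' @export
agent_observe.tomrep_agent <- function(agent, a_self, a_op, reward) agent

#' @export
print.tomrep_agent <- function(x, ...) {
  cat(sprintf("<%s agent (%s), beta=%.3g, bias=%.3g>\n",
              x$name, x$role, x$policy$beta, x$policy$bias))
  invisible(x)
}

# -- RB ---------------------------------------------------------------------

#' @export
agent_reset.rb_agent <- function(agent) {
  pref <- if (is.null(agent$preferred)) sample(0:1, 1) else agent$preferred
  n_pref <- round(agent$bias_level * agent$n_trials)
  sched <- rep(1L - pref, agent$n_trials)
  sched[sample.int(agent$n_trials, n_pref)] <- pref
  agent$schedule <- sched
  agent$t <- 0L
  agent
}

#' @export
agent_act.rb_agent <- function(agent) {
  t <- agent$t + 1L
  if (t > length(agent$schedule)) stop("RB schedule exhausted")
  agent$schedule[t]
}

#' @export
agent_predict.rb_agent <- function(agent) stop("RB has no opponent prediction")

#' @export
agent_delta_v.rb_agent <- function(agent) stop("RB has no value difference")

#' @export
agent_observe.rb_agent <- function(agent, a_self, a_op, reward) {
  agent$t <- agent$t + 1L
  agent
}

# -- BN ---------------------------------------------------------------------

#' @export
agent_reset.bn_agent <- function(agent) agent

#' @export
agent_delta_v.bn_agent <- function(agent) 0

#' @export
agent_predict.bn_agent <- function(agent) 0.5

# -- WSLS -------------------------------------------------------------------

#' @export
agent_reset.wsls_agent <- function(agent) { agent$state <- wsls_state(); agent }

#' @export
agent_delta_v.wsls_agent <- function(agent) diff(agent$state$values)

#' @export
agent_predict.wsls_agent <- function(agent) stop("WSLS is value-based")

#' @export
agent_observe.wsls_agent <- function(agent, a_self, a_op, reward) {
  agent$state <- wsls_update(agent$state, a_self, reward)
  agent
}

# -- RL ---------------------------------------------------------------------

#' @export
agent_reset.rl_agent <- function(agent) {
  agent$state <- rl_state(alpha = agent$state$alpha)
  agent
}

#' @export
agent_delta_v.rl_agent <- function(agent) diff(agent$state$values)

#' @export
agent_predict.rl_agent <- function(agent) stop("RL is value-based")

#' @export
agent_observe.rl_agent <- function(agent, a_self, a_op, reward) {
  agent$state <- rl_update(agent$state, a_self, reward)
  agent
}

# -- influence --------------------------------------------------------------

#' @export
agent_reset.influence_agent <- function(agent) {
  agent$state <- influence_state(eta = agent$state$eta,
                                 influence_weight = agent$state$influence_weight,
                                 beta_inf = agent$state$beta_inf)
  agent
}

#' @export
agent_predict.influence_agent <- function(agent) agent$state$p_op

#' @export
agent_observe.influence_agent <- function(agent, a_self, a_op, reward) {
  agent$state <- influence_update(agent$state, a_op = a_op, a_self = a_self)
  agent
}

# -- k-ToM ------------------------------------------------------------------

#' @export
agent_reset.tom_agent <- function(agent) {
  agent$ptr <- cpp_tom_new(agent$k, agent$sigma, agent$policy$beta,
                           role_sign(agent$role))
  agent
}

#' @export
agent_predict.tom_agent <- function(agent) {
  if (is.null(agent$ptr)) stop("k-ToM agent must be reset before use")
  cpp_tom_predict(agent$ptr)
}

#' @export
agent_observe.tom_agent <- function(agent, a_self, a_op, reward) {
  cpp_tom_update(agent$ptr, a_self, a_op)
  agent
}

#' Inspect a k-ToM agent's belief state
#'
#' @param agent A reset `agent_tom()` object.
#' @return For `k = 0` the scalar belief (`mu`, `sigma2`); for `k >= 1` the
#'   level posterior, per-level means over `x = (log sigma, log beta)`,
#'   per-level covariance matrices, and the covariance-repair count.
#' @export
tom_state <- function(agent) {
  stopifnot(inherits(agent, "tom_agent"))
  if (is.null(agent$ptr)) stop("k-ToM agent must be reset before use")
  cpp_tom_state(agent$ptr)
}

#' Replay a simulated opponent level
#'
#' Returns the probability that a `kappa`-ToM opponent with hidden states
#' fixed at `x = (log sigma, log beta)` would assign to its own action 1 on
#' the next trial, obtained by replaying that learner over the full history.
#' The history is given from the focal agent's perspective (`a_self` is the
#' focal player's own sequence); the simulated level plays the opposite
#' role.
#'
#' @param kappa Simulated sophistication level (0..2).
#' @param x Numeric length-2 hidden states `(log sigma, log beta)`.
#' @param a_self,a_op Binary action histories (equal length, possibly empty).
#' @param role Focal agent's role; the level plays the other role.
#' @return Probability in (0, 1).
#' @export
ktom_simulate_level <- function(kappa, x, a_self = integer(0),
                                a_op = integer(0), role = "seeker") {
  stopifnot(length(a_self) == length(a_op),
            all(a_self %in% 0:1), all(a_op %in% 0:1))
  cpp_simulate_level(as.integer(kappa), as.numeric(x),
                     -role_sign(role), as.integer(a_self), as.integer(a_op))
}
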