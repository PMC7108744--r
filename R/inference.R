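#' Model specification for the eight-strategy repertoire
#'
#' Each candidate model's free parameters live in an unconstrained
#' transformed space with independent standard-normal priors: `log` for
#' volatilities and temperatures, `logit` for rates and weights, identity
#' for the bias.
#'
#' @param name One of [repertoire_models()].
#' @return A list with elements `name`, `par_names` (natural-space names),
#'   `n_par`, and `to_natural(z)`.
#' @export
model_spec <- function(name) {
  name <- match.arg(name, TOMREP_MODELS)
  spec <- switch(name,
    "BN" = list(par_names = "bias",
                to_natural = function(z) list(bias = z[1])),
    "WSLS" = list(par_names = c("beta", "bias"),
                  to_natural = function(z) list(beta = exp(z[1]), bias = z[2])),
    "RL" = list(par_names = c("alpha", "beta", "bias"),
                to_natural = function(z) list(alpha = sigmoid(z[1]),
                                              beta = exp(z[2]), bias = z[3])),
    "0-ToM" = ,
    "1-ToM" = ,
    "2-ToM" = ,
    "3-ToM" = list(par_names = c("sigma", "beta", "bias"),
                   to_natural = function(z) list(sigma = exp(z[1]),
                                                 beta = exp(z[2]), bias = z[3])),
    "Inf" = list(par_names = c("eta", "influence_weight", "beta", "bias"),
                 to_natural = function(z) list(eta = sigmoid(z[1]),
                                               influence_weight = sigmoid(z[2]),
                                               beta = exp(z[3]), bias = z[4])))
  spec$name <- name
  spec$n_par <- length(spec$par_names)
  spec
}

session_vectors <- function(session) {
  list(a_self = as.integer(session$a_self),
       a_op = as.integer(session$a_op),
       reward = as.numeric(session$reward))
}

#' Session log likelihood of a candidate model
#'
#' Sum over trials of the log probability of the focal player's observed
#' action given the history so far.  The model's internal state is updated
#' with both observed actions (and the observed reward) after every trial:
#' fitting replays the participant's observed opponent, it never simulates
#' one.
#'
#' @param session Session data frame (one session).
#' @param model Model name or a [model_spec()].
#' @param theta Parameter vector in transformed space.
#' @param role Focal player's role (default `"seeker"`).
#' @return The log likelihood (<= 0).
#' @export
session_log_likelihood <- function(session, model, theta, role = "seeker") {
  if (is.character(model)) model <- model_spec(model)
  if (length(theta) != model$n_par)
    stop(sprintf("%s expects %d parameters, got %d", model$name, model$n_par,
                 length(theta)))
  v <- session_vectors(session)
  p <- model$to_natural(theta)
  rs <- role_sign(role)
  ll <- switch(model$name,
    "BN" = {
      p1 <- sigmoid(p$bias)
      sum(v$a_self) * log(p1) + sum(1 - v$a_self) * log(1 - p1)
    },
    "WSLS" = cpp_loglik_wsls(p$beta, p$bias, v$a_self, v$reward),
    "RL" = cpp_loglik_rl(p$alpha, p$beta, p$bias, v$a_self, v$reward),
    "Inf" = cpp_loglik_inf(p$eta, p$influence_weight, p$beta, p$bias, rs,
                           v$a_self, v$a_op, 1e-4),
    "0-ToM" = cpp_loglik_ktom(0L, p$sigma, p$beta, p$bias, rs, v$a_self, v$a_op),
    "1-ToM" = cpp_loglik_ktom(1L, p$sigma, p$beta, p$bias, rs, v$a_self, v$a_op),
    "2-ToM" = cpp_loglik_ktom(2L, p$sigma, p$beta, p$bias, rs, v$a_self, v$a_op),
    "3-ToM" = cpp_loglik_ktom(3L, p$sigma, p$beta, p$bias, rs, v$a_self, v$a_op))
  if (!is.finite(ll)) stop("non-finite likelihood for model ", model$name)
  ll
}

#' Inference settings
#'
#' @param n_restarts Number of optimizer starts (first at the prior mode,
#'   the rest drawn from the prior under `seed`).
#' @param maxit Maximum BFGS iterations per start.
#' @param seed Seed for the restart draws (makes fits deterministic).
#' @param prior_sd Standard deviation of the zero-mean Gaussian prior on
#'   every transformed parameter.
#' @return A settings list.
#' @export
inference_config <- function(n_restarts = 8, maxit = 100, seed = 1,
                             prior_sd = 1) {
  stopifnot(n_restarts >= 1, maxit >= 1, prior_sd > 0)
  list(n_restarts = n_restarts, maxit = maxit, seed = seed,
       prior_sd = prior_sd)
}

#' Fit one model to one session (MAP + Laplace evidence)
#'
#' Maximum a posteriori estimation under standard-normal priors in
#' transformed space, by multi-start BFGS, followed by a Laplace
#' approximation of the log model evidence:
#' `log p(a | m) ~ log p(a | theta*) + log prior(theta*) + d/2 log(2 pi)
#'  - 1/2 log det H`, with `H` the negative Hessian of the log posterior at
#' the MAP.  If `H` is not positive definite the fit falls back to a
#' BIC-style evidence and flags it in the diagnostics.
#'
#' @param session One session data frame.
#' @param model Model name or [model_spec()].
#' @param config An [inference_config()].
#' @param role Focal player's role.
#' @return A `fit_result` list: `log_evidence`, `map` (transformed space),
#'   `map_natural`, `posterior_sd`, `diagnostics`.
#' @export
fit_session <- function(session, model, config = inference_config(),
                        role = "seeker") {
  if (is.character(model)) model <- model_spec(model)
  d <- model$n_par
  prior_sd <- if (is.null(config$prior_sd)) 1 else config$prior_sd
  neg_obj <- function(z) {
    ll <- tryCatch(session_log_likelihood(session, model, z, role),
                   error = function(e) -Inf)
    val <- ll + sum(dnorm(z, 0, prior_sd, log = TRUE))
    if (!is.finite(val)) 1e10 else -val
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  starts <- rbind(rep(0, d),
                  matrix(rnorm((config$n_restarts - 1) * d, 0, prior_sd),
                         ncol = d))
  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], neg_obj, method = "BFGS",
            control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        optim(starts[i, ], neg_obj, method = "Nelder-Mead",
              control = list(maxit = 5 * config$maxit)),
        error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed for model ", model$name)
  z_map <- best$par
  log_post <- -best$value
  H <- tryCatch(optimHess(z_map, neg_obj), error = function(e) NULL)
  bic_fallback <- FALSE
  post_sd <- rep(NA_real_, d)
  n <- nrow(session)
  chol_H <- if (!is.null(H)) tryCatch(chol((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(chol_H)) {
    bic_fallback <- TRUE
    log_ev <- session_log_likelihood(session, model, z_map, role) -
      d / 2 * log(n)
  } else {
    log_det_H <- 2 * sum(log(diag(chol_H)))
    log_ev <- log_post + d / 2 * log(2 * pi) - 0.5 * log_det_H
    post_sd <- sqrt(diag(chol2inv(chol_H)))
  }
  capped <- log_ev > 0
  if (capped) log_ev <- 0
  structure(list(
    log_evidence = log_ev,
    map = setNames(z_map, model$par_names),
    map_natural = model$to_natural(z_map),
    posterior_sd = setNames(post_sd, model$par_names),
    diagnostics = list(model = model$name, convergence = best$convergence,
                       n_restarts = config$n_restarts, n_failed = n_fail,
                       bic_fallback = bic_fallback, capped = capped)),
    class = "fit_result")
}

session_keys <- function(sessions) {
  unique(sessions[c("subject_id", "opponent", "framing", "repetition")])
}

#' Fit all models to all sessions
#'
#' @param sessions Stacked session data frame.
#' @param models Character vector of model names (default: all eight).
#' @param config An [inference_config()].
#' @param role Focal player's role.
#' @param previous Optional evidence table from an earlier (partial) run;
#'   already-fitted (session, model) pairs are reused.
#' @param verbose Print per-subject progress.
#' @return The evidence table: one row per session x model with columns
#'   `subject_id`, `opponent`, `framing`, `repetition`, `model`,
#'   `log_evidence`; aggregate fit diagnostics (counts of BIC fallbacks,
#'   capped evidences, optimizer failures) in `attr(, "diagnostics")`.
#' @export
fit_cohort <- function(sessions, models = repertoire_models(),
                       config = inference_config(), role = "seeker",
                       previous = NULL, verbose = FALSE) {
  keys <- session_keys(sessions)
  out <- vector("list", nrow(keys) * length(models))
  idx <- 0L
  diag_counts <- c(n_fits = 0L, bic_fallback = 0L, capped = 0L,
                   optimizer_failures = 0L)
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- sessions$subject_id == k$subject_id &
      sessions$opponent == k$opponent & sessions$framing == k$framing &
      sessions$repetition == k$repetition
    sess <- sessions[sel, ]
    sess <- sess[order(sess$trial), ]
    if (verbose && (i %% 16 == 1))
      message(sprintf("fitting session %d/%d", i, nrow(keys)))
    for (m in models) {
      idx <- idx + 1L
      if (!is.null(previous)) {
        prev <- previous[previous$subject_id == k$subject_id &
                           previous$opponent == k$opponent &
                           previous$framing == k$framing &
                           previous$repetition == k$repetition &
                           previous$model == m, , drop = FALSE]
        if (nrow(prev) == 1) { out[[idx]] <- prev; next }
      }
      fit <- fit_session(sess, m, config, role)
      diag_counts <- diag_counts + c(1L, fit$diagnostics$bic_fallback,
                                     fit$diagnostics$capped,
                                     fit$diagnostics$n_failed)
      out[[idx]] <- data.frame(
        subject_id = k$subject_id, opponent = k$opponent, framing = k$framing,
        repetition = k$repetition, model = m, log_evidence = fit$log_evidence,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), diagnostics = as.list(diag_counts))
}

#' Check an evidence table for completeness
#'
#' @param evidence Evidence table from [fit_cohort()].
#' @param models Expected model set.
#' @return Invisibly `evidence`; stops listing missing session x model pairs.
#' @export
validate_evidence <- function(evidence, models = repertoire_models()) {
  counts <- table(interaction(evidence$subject_id, evidence$opponent,
                              evidence$framing, evidence$repetition, drop = TRUE))
  bad <- names(counts)[counts != length(models)]
  if (length(bad))
    stop("incomplete evidence for sessions: ", paste(head(bad, 5), collapse = "; "))
  if (!all(evidence$model %in% models)) stop("unknown model names in evidence")
  if (any(!is.finite(evidence$log_evidence))) stop("non-finite log evidences")
  invisible(evidence)
}

#' Posterior model probabilities for one session
#'
#' Softmax of log evidences plus log prior (uniform by default), computed
#' stably by max subtraction.
#'
#' @param log_evidence Named numeric vector of log evidences (one per
#'   model), or a one-session slice of the evidence table.
#' @param prior Prior simplex over the same models (default uniform).
#' @return Named probability simplex over the models.
#' @export
model_posterior <- function(log_evidence, prior = NULL) {
  if (is.data.frame(log_evidence))
    log_evidence <- setNames(log_evidence$log_evidence, log_evidence$model)
  if (any(!is.finite(log_evidence))) stop("log evidences must be finite")
  if (is.null(prior)) prior <- rep(1 / length(log_evidence), length(log_evidence))
  if (length(prior) != length(log_evidence) || any(prior < 0))
    stop("prior must be a simplex over the same models")
  lw <- log_evidence + log(prior)
  w <- exp(lw - max(lw))
  w / sum(w)
}
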