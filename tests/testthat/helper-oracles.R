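# Independent oracles used across tests.

# Dense grid Bayes filter over the opponent's choice log-odds x with Gaussian
# diffusion (variance `sigma`) and Bernoulli(s(x)) observations; prior N(0,1).
# Returns, per trial, the posterior mean of x and of s(x).
grid_bayes_filter <- function(a_ops, sigma, lo = -10, hi = 10, by = 0.01) {
  x <- seq(lo, hi, by = by)
  K <- outer(x, x, function(xt, xp) dnorm(xt, xp, sqrt(sigma))) * by
  w <- dnorm(x, 0, 1)
  w <- w / sum(w)
  mu <- p <- numeric(length(a_ops))
  for (t in seq_along(a_ops)) {
    w <- as.vector(K %*% w)
    lik <- if (a_ops[t] == 1) plogis(x) else 1 - plogis(x)
    w <- w * lik
    w <- w / sum(w)
    mu[t] <- sum(x * w)
    p[t] <- sum(plogis(x) * w)
  }
  list(mu = mu, p = p)
}

# Gauss-Hermite quadrature for E[s(x)], x ~ N(mu, var) (31 nodes).
gauss_hermite_sigmoid <- function(mu, var, n = 31) {
  gh <- function(n) {
    i <- seq_len(n - 1)
    b <- sqrt(i / 2)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
  }
  q <- gh(n)
  sum(q$weights / sqrt(pi) * plogis(mu + sqrt(2 * var) * q$nodes))
}

# 1-D / 2-D grid marginalization of the model evidence (prior N(0, prior_sd))
grid_evidence_1d <- function(session, model, lo = -6, hi = 6, by = 0.01,
                             prior_sd = 1) {
  g <- seq(lo, hi, by = by)
  ll <- vapply(g, function(z) session_log_likelihood(session, model, z),
               numeric(1))
  lp <- ll + dnorm(g, 0, prior_sd, log = TRUE)
  m <- max(lp)
  m + log(sum(exp(lp - m)) * by)
}

grid_evidence_2d <- function(session, model, lo = -5, hi = 5, by = 0.05,
                             prior_sd = 1) {
  g <- seq(lo, hi, by = by)
  LL <- outer(g, g, Vectorize(function(z1, z2)
    session_log_likelihood(session, model, c(z1, z2))))
  LP <- LL + outer(dnorm(g, 0, prior_sd, log = TRUE),
                   dnorm(g, 0, prior_sd, log = TRUE), "+")
  m <- max(LP)
  m + log(sum(exp(LP - m)) * by^2)
}

# point-mass posterior over the eight models
point_mass_posterior <- function(model) {
  p <- setNames(rep(0, length(repertoire_models())), repertoire_models())
  p[model] <- 1
  p
}

# build a complete 16-session evidence table for one subject from a map
# (opponent|framing|repetition) -> model name given huge evidence
evidence_from_strategies <- function(subject, strategy_of) {
  rows <- list()
  for (o in c("RB", "0-ToM", "1-ToM", "2-ToM"))
    for (f in c("social", "non-social"))
      for (r in c("1", "2")) {
        m <- strategy_of(o, f, r)
        le <- ifelse(repertoire_models() == m, -10, -40)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = subject, opponent = o, framing = f, repetition = r,
          model = repertoire_models(), log_evidence = le,
          stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}
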