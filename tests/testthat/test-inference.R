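make_session <- function(strategy = "WSLS", opponent = "RB", seed = 1,
                         params = list()) {
  p <- utils::modifyList(default_strategy_params(), params)
  seeker <- agent_from_strategy(strategy, "seeker", p)
  hider <- if (opponent == "RB") agent_rb("hider") else
    tournament_agent(opponent, "hider")
  play_game(seeker, hider, seed = seed, opponent = opponent)
}

test_that("likelihoods have their closed-form anchors", {
  sess <- make_session("BN", seed = 5)
  expect_equal(session_log_likelihood(sess, "BN", 0), 60 * log(0.5),
               tolerance = 1e-12)
  # parameter-count contract
  expect_error(session_log_likelihood(sess, "RL", c(0, 0)), "3 parameters")
  # data generated by a decisive WSLS is better explained by WSLS at truth
  sessw <- make_session("WSLS", seed = 6, params = list(beta = 0.2))
  ll_w <- session_log_likelihood(sessw, "WSLS", c(log(0.2), 0))
  expect_gt(ll_w, 60 * log(0.5))
})

test_that("0-ToM likelihood is symmetric under relabeling both actions", {
  sess <- make_session("0-ToM", opponent = "0-ToM", seed = 7)
  flipped <- sess
  flipped$a_self <- 1L - flipped$a_self
  flipped$a_op <- 1L - flipped$a_op
  flipped$reward <- payoff("seeker", flipped$a_self, flipped$a_op)
  theta <- c(log(0.4), log(0.7), 0)  # zero bias
  expect_equal(session_log_likelihood(sess, "0-ToM", theta),
               session_log_likelihood(flipped, "0-ToM", theta),
               tolerance = 1e-9)
})

test_that("R stepper path and C++ likelihood path agree", {
  # replaying the RL updates in R reproduces the C++ session likelihood
  sess <- make_session("RL", seed = 8)
  alpha <- 0.35; beta <- 0.8; bias <- 0.2
  st <- rl_state(alpha = alpha)
  ll <- 0
  for (t in seq_len(nrow(sess))) {
    p1 <- plogis((diff(st$values) + bias) / beta)
    ll <- ll + log(ifelse(sess$a_self[t] == 1, p1, 1 - p1))
    st <- rl_update(st, sess$a_self[t], sess$reward[t])
  }
  theta <- c(qlogis(alpha), log(beta), bias)
  expect_equal(session_log_likelihood(sess, "RL", theta), ll, tolerance = 1e-9)
  # same for the influence learner
  sess <- make_session("Inf", opponent = "1-ToM", seed = 9)
  eta <- 0.4; w <- 0.25; beta <- 0.6; bias <- -0.1
  st <- influence_state(0.5, eta = eta, influence_weight = w, beta_inf = beta)
  ll <- 0
  for (t in seq_len(nrow(sess))) {
    dv <- expected_value_difference(st$p_op, "seeker")
    p1 <- plogis((dv + bias) / beta)
    ll <- ll + log(ifelse(sess$a_self[t] == 1, p1, 1 - p1))
    st <- influence_update(st, a_op = sess$a_op[t], a_self = sess$a_self[t])
  }
  theta <- c(qlogis(eta), qlogis(w), log(beta), bias)
  expect_equal(session_log_likelihood(sess, "Inf", theta), ll, tolerance = 1e-9)
})

test_that("Laplace evidence matches grid marginalization for small models", {
  set.seed(12)
  cfg <- inference_config(n_restarts = 4, maxit = 80)
  for (i in 1:3) {
    sess <- make_session("BN", seed = 20 + i)
    fit <- fit_session(sess, "BN", cfg)
    expect_lt(abs(fit$log_evidence - grid_evidence_1d(sess, "BN")), 1.0)
    expect_lte(fit$log_evidence, 0)
    sessw <- make_session("WSLS", seed = 30 + i, params = list(beta = 0.3))
    fitw <- fit_session(sessw, "WSLS", cfg)
    expect_lt(abs(fitw$log_evidence - grid_evidence_2d(sessw, "WSLS")), 1.0)
  }
})

test_that("fits are deterministic and BN wins on unbiased coin-flip data", {
  sess <- make_session("BN", seed = 41)
  cfg <- inference_config(n_restarts = 3, maxit = 60)
  f1 <- fit_session(sess, "RL", cfg)
  f2 <- fit_session(sess, "RL", cfg)
  expect_identical(f1$log_evidence, f2$log_evidence)
  expect_identical(f1$map, f2$map)
  # Occam: on BN(bias = 0) data the 1-parameter model beats the
  # 3-parameter models on average
  evs <- sapply(1:6, function(i) {
    s <- make_session("BN", seed = 100 + i)
    c(bn = fit_session(s, "BN", cfg)$log_evidence,
      rl = fit_session(s, "RL", cfg)$log_evidence,
      tom0 = fit_session(s, "0-ToM", cfg)$log_evidence)
  })
  expect_gt(mean(evs["bn", ] - evs["rl", ]), 0)
  expect_gt(mean(evs["bn", ] - evs["tom0", ]), 0)
})

test_that("fit_cohort produces a complete, reusable evidence table", {
  spec <- cohort_spec(n_per_group = 2, seed = 3)
  coh <- generate_cohort(spec)
  two <- coh$sessions[coh$sessions$subject_id %in% c("S01", "S03"), ]
  cfg <- inference_config(n_restarts = 1, maxit = 30)
  ev <- fit_cohort(two, config = cfg)
  expect_equal(nrow(ev), 2 * 16 * 8)
  expect_silent(validate_evidence(ev))
  # resuming from the full table is a no-op
  ev2 <- fit_cohort(two, config = cfg, previous = ev)
  expect_equal(ev2$log_evidence, ev$log_evidence)
  # incomplete tables are rejected
  expect_error(validate_evidence(ev[-1, ]), "incomplete")
})

test_that("model posterior is a stable softmax of the evidences", {
  le <- setNames(rep(-40, 8), repertoire_models())
  expect_equal(unname(model_posterior(le)), rep(1 / 8, 8))
  le["Inf"] <- -20
  expect_gt(model_posterior(le)["Inf"], 0.999)
  # shift invariance
  expect_equal(model_posterior(le), model_posterior(le + 123.4))
  # prior reweighting
  pr <- c(0.5, rep(0.5 / 7, 7))
  expect_gt(model_posterior(setNames(rep(-40, 8), repertoire_models()), pr)[1],
            0.49)
  expect_error(model_posterior(c(a = -Inf, b = -2)), "finite")
})
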