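test_that("0-ToM update matches the closed-form recursion", {
  s <- tom0_update(tom0_state(0, 1, 0.5), a_op = 1)
  expect_equal(s$sigma2, 1 / (1 / 1.5 + 0.25), tolerance = 1e-12)
  expect_equal(s$mu, s$sigma2 * 0.5, tolerance = 1e-12)
  # near-zero prediction error when the belief is already extreme
  s2 <- tom0_update(tom0_state(20, 0.5, 0.1), a_op = 1)
  expect_lt(abs(s2$mu - 20), 1e-6)
  # variance stays positive and shrinks under repeated consistent evidence
  st <- tom0_state(0, 1, 0.1)
  for (i in 1:60) {
    st <- tom0_update(st, 1)
    expect_gt(st$sigma2, 0)
  }
  expect_gt(plogis(st$mu), 0.9)
})

test_that("influence update reproduces hand-computed values", {
  st <- influence_state(0.5, eta = 0.5, influence_weight = 0.2, beta_inf = 1)
  expect_equal(influence_update(st, a_op = 1, a_self = 1)$p_op, 0.70,
               tolerance = 1e-12)
  # zero influence weight reduces to exponential smoothing
  st <- influence_state(0.3, eta = 0.25, influence_weight = 0, beta_inf = 1)
  expect_equal(influence_update(st, a_op = 1, a_self = 0)$p_op,
               0.3 + 0.25 * 0.7, tolerance = 1e-12)
  # pure influence term: eta = 0, beta = 0, a_self = 0 moves p up by w/4
  st <- influence_state(0.5, eta = 0, influence_weight = 0.2, beta_inf = 0)
  expect_equal(influence_update(st, a_op = 0, a_self = 0)$p_op,
               0.5 + 0.2 * 0.25, tolerance = 1e-12)
  # clipping keeps the estimate inside (0, 1) and is counted
  st <- influence_state(1 - 1e-4, eta = 1, influence_weight = 0, beta_inf = 1)
  st <- influence_update(st, a_op = 1, a_self = 0)
  expect_lte(st$p_op, 1 - st$eps)
  expect_gte(st$p_op, st$eps)
})

test_that("RL update changes only the chosen value and stays bounded", {
  st <- rl_state(alpha = 0.5)
  st <- rl_update(st, a_self = 1, reward = 1)
  expect_equal(st$values, c(0, 0.5))
  expect_equal(rl_update(st, a_self = 1, reward = st$values[2])$values,
               st$values)  # zero prediction error
  # alpha = 1 jumps straight to the reward (WSLS-like on the chosen arm)
  st <- rl_update(rl_state(alpha = 1), a_self = 0, reward = 1)
  expect_equal(st$values, c(1, 0))
  # values bounded in [0,1] under rewards in {0,1}
  st <- rl_state(alpha = 0.7)
  set.seed(1)
  for (i in 1:200) {
    st <- rl_update(st, rbinom(1, 1, 0.5), rbinom(1, 1, 0.5))
    expect_true(all(st$values >= 0 & st$values <= 1))
  }
})

test_that("WSLS sets signed values so stay-after-win is most probable", {
  st <- wsls_update(wsls_state(), a_self = 1, reward = 1)
  expect_equal(st$values, c(-1, 1))  # stay on 1
  st <- wsls_update(st, a_self = 1, reward = 0)
  expect_equal(st$values, c(1, -1))  # switch
  # idempotent under repeated identical win
  st1 <- wsls_update(wsls_state(), 1, 1)
  expect_equal(wsls_update(st1, 1, 1), st1)
})

test_that("RB schedule carries exactly the 65% bias and ignores the rng", {
  set.seed(7)
  rb <- agent_reset(agent_rb(n_trials = 60, bias_level = 0.65, preferred = 1))
  expect_equal(sum(rb$schedule == 1), round(0.65 * 60))
  expect_equal(length(rb$schedule), 60)
  # deterministic action = schedule, independent of RNG state
  a1 <- agent_act(rb)
  set.seed(999)
  expect_identical(agent_act(rb), a1)
  expect_identical(a1, rb$schedule[1])
})

test_that("BN with zero bias plays uniformly; bias shifts its choice", {
  bn <- agent_reset(agent_bn("seeker", bias = 0))
  expect_equal(choice_probability(agent_delta_v(bn), bn$policy), 0.5)
  bn2 <- agent_reset(agent_bn("seeker", bias = 2))
  expect_gt(choice_probability(agent_delta_v(bn2), bn2$policy), 0.85)
})

test_that("value-based agents become greedy as temperature vanishes", {
  ag <- agent_wsls("seeker", beta = 1e-3)
  ag <- agent_reset(ag)
  ag <- agent_observe(ag, a_self = 1, a_op = 1, reward = 1)
  set.seed(2)
  acts <- replicate(50, agent_act(ag))
  expect_true(all(acts == 1))
})

test_that("strategy factory covers the full repertoire", {
  for (m in repertoire_models()) {
    ag <- agent_reset(agent_from_strategy(m, "seeker"))
    expect_s3_class(ag, "tomrep_agent")
    expect_identical(ag$name, m)
    a <- agent_act(ag)
    expect_true(a %in% 0:1)
  }
})

test_that("agent configuration blocks validate their keys", {
  ag <- agent_from_config(list(type = "Inf", role = "hider", eta = 0.3,
                               beta = 0.5))
  expect_s3_class(ag, "influence_agent")
  expect_equal(ag$state$eta, 0.3)
  ag2 <- agent_from_config(list(type = "k-ToM", k = 2, sigma = 0.2))
  expect_s3_class(ag2, "tom_agent")
  expect_equal(ag2$k, 2L)
  expect_s3_class(agent_from_config(list(type = "RB", bias_level = 0.65)),
                  "rb_agent")
  expect_error(agent_from_config(list(type = "RL", gamma = 0.9)), "gamma")
  expect_error(agent_from_config(list(alpha = 1)), "type")
})
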