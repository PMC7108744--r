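# Recursive mentalizing learners: oracle checks and belief invariants.

test_that("0-ToM belief tracks a dense grid Bayes filter at slow drift", {
  # the one-step update's deviation from exact inference grows with the
  # assumed drift rate; the 0.05 band holds in the slow-drift regime
  set.seed(11)
  for (sigma in c(0.05, 0.1)) {
    for (r in 1:3) {
      a <- rbinom(60, 1, 0.5)
      oracle <- grid_bayes_filter(a, sigma)
      st <- tom0_state(0, 1, sigma)
      p_hat <- numeric(60)
      for (t in 1:60) {
        st <- tom0_update(st, a[t])
        p_hat[t] <- plogis(st$mu / sqrt(1 + (3 / pi^2) * st$sigma2))
      }
      expect_lt(max(abs(p_hat - oracle$p)), if (sigma <= 0.05) 0.05 else 0.08)
    }
  }
})

test_that("moment-approximated sigmoid expectation matches quadrature", {
  for (mu in c(-4, -1, 0, 0.5, 2, 4)) {
    for (v in c(0.1, 1, 4)) {
      approx <- plogis(mu / sqrt(1 + (3 / pi^2) * v))
      exact <- gauss_hermite_sigmoid(mu, v)
      expect_lt(abs(approx - exact), 0.03)
    }
  }
  # prediction shrinks toward 0.5 as variance grows at fixed mu != 0
  st_small <- tom0_state(4, 0.1, 0.01)
  st_big <- tom0_state(4, 4, 0.01)
  expect_equal(tom0_predict(tom0_state(0, 3, 1)), 0.5)
  expect_gt(tom0_predict(st_small), 0.95)
  expect_lt(tom0_predict(st_big), tom0_predict(st_small))
  expect_gt(tom0_predict(st_big), 0.5)
})

test_that("simulated-level replay has the stated fixed points", {
  # flat prior, empty history
  expect_equal(ktom_simulate_level(0, c(0, 0)), 0.5)
  # a 0-ToM hider facing a seeker that always played 1 avoids 1
  xs <- rep(1L, 20)
  ys <- rbinom(20, 1, 0.5)
  p <- ktom_simulate_level(0, c(0, 0), a_self = xs, a_op = ys, role = "seeker")
  expect_lt(p, 0.5)
  # determinism
  set.seed(3)
  xs <- rbinom(30, 1, 0.5); ys <- rbinom(30, 1, 0.5)
  p1 <- ktom_simulate_level(1, c(log(0.5), log(0.8)), xs, ys)
  p2 <- ktom_simulate_level(1, c(log(0.5), log(0.8)), xs, ys)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 < 1)
})

test_that("k-ToM level posterior is a simplex and beliefs stay PD", {
  set.seed(17)
  for (k in 1:3) {
    for (rep in 1:(if (k == 3) 20 else 100)) {
      ag <- agent_reset(agent_tom(k, "seeker", sigma = 0.5, beta = 0.5))
      a <- rbinom(60, 1, 0.5); b <- rbinom(60, 1, 0.5)
      for (t in 1:60) ag <- agent_observe(ag, a[t], b[t], payoff("seeker", a[t], b[t]))
      st <- tom_state(ag)
      expect_equal(sum(st$level_posterior), 1, tolerance = 1e-10)
      expect_true(all(st$level_posterior >= 0))
      for (kap in seq_len(k)) {
        S <- st$Sigma[[kap]]
        expect_equal(S[1, 2], S[2, 1], tolerance = 1e-9)
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        expect_true(all(ev > 0))
      }
    }
  }
})

test_that("1-ToM keeps a degenerate level posterior", {
  ag <- agent_reset(agent_tom(1, "seeker"))
  set.seed(4)
  for (t in 1:40) {
    a <- rbinom(1, 1, 0.5); b <- rbinom(1, 1, 0.5)
    ag <- agent_observe(ag, a, b, payoff("seeker", a, b))
    expect_identical(tom_state(ag)$level_posterior, 1)
  }
})

test_that("2-ToM identifies a true 1-ToM opponent's sophistication", {
  set.seed(42)
  a2 <- agent_reset(agent_tom(2, "seeker", 0.1, 0.5))
  a1 <- agent_reset(agent_tom(1, "hider", 0.1, 0.5))
  lam1 <- numeric(500)
  for (t in 1:500) {
    x <- agent_act(a2); y <- agent_act(a1)
    lam1[t] <- tom_state(a2)$level_posterior[2]
    a2 <- agent_observe(a2, x, y, payoff("seeker", x, y))
    a1 <- agent_observe(a1, y, x, payoff("hider", y, x))
  }
  expect_gt(mean(lam1[401:500]), 0.5)
})

test_that("k-ToM mixture prediction equals the level-wise mixture", {
  set.seed(9)
  ag <- agent_reset(agent_tom(2, "seeker", 0.3, 0.5))
  for (t in 1:25) {
    a <- rbinom(1, 1, 0.5); b <- rbinom(1, 1, 0.5)
    ag <- agent_observe(ag, a, b, payoff("seeker", a, b))
  }
  d <- tomrep:::cpp_tom_debug(ag$ptr)
  st <- tom_state(ag)
  expect_equal(d$p_op, sum(st$level_posterior * d$pk), tolerance = 1e-12)
  expect_equal(agent_predict(ag), d$p_op, tolerance = 1e-12)
})

test_that("level posterior is unmoved when levels predict equally well", {
  # before any history both simulated levels predict 0.5, so the first
  # observation carries no information about the opponent's depth
  ag <- agent_reset(agent_tom(2, "seeker", 0.5, 0.5))
  ag <- agent_observe(ag, a_self = 1, a_op = 0, reward = 0)
  expect_equal(tom_state(ag)$level_posterior, c(0.5, 0.5), tolerance = 1e-9)
})
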