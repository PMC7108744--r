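test_that("flexibility has its closed-form fixed points", {
  u <- rep(1 / 8, 8)
  expect_equal(flexibility(u, u), 0.875)
  p1 <- point_mass_posterior("Inf")
  expect_equal(flexibility(p1, p1), 0)
  expect_equal(flexibility(p1, point_mass_posterior("1-ToM")), 1)
  # symmetry and bounds on random simplices
  set.seed(3)
  for (i in 1:25) {
    a <- rexp(8); a <- setNames(a / sum(a), repertoire_models())
    b <- rexp(8); b <- setNames(b / sum(b), repertoire_models())
    expect_equal(flexibility(a, b), flexibility(b, a))
    f <- flexibility(a, b)
    expect_gte(f, 0); expect_lte(f, 1)
  }
  expect_error(flexibility(u[1:7], u), "different model sets")
})

test_that("ToM sophistication is the expected recursion depth", {
  expect_equal(tom_sophistication(point_mass_posterior("2-ToM")), 2)
  p <- point_mass_posterior("1-ToM") / 2 + point_mass_posterior("2-ToM") / 2
  expect_equal(tom_sophistication(p), 1.5)
  expect_equal(tom_sophistication(point_mass_posterior("Inf")), 0)
  # linear in the posterior; invariant to mass shuffling among non-ToM models
  q1 <- c(BN = 0.3, WSLS = 0.1, RL = 0, "0-ToM" = 0, "Inf" = 0.1,
          "1-ToM" = 0.5, "2-ToM" = 0, "3-ToM" = 0)
  q2 <- c(BN = 0, WSLS = 0.2, RL = 0.2, "0-ToM" = 0, "Inf" = 0.1,
          "1-ToM" = 0.5, "2-ToM" = 0, "3-ToM" = 0)
  expect_equal(tom_sophistication(q1), tom_sophistication(q2))
  # renormalized variant conditions on the ToM subset
  expect_equal(tom_sophistication(q1, renormalize = TRUE), 1)
})

test_that("participant profiles compose the unit cases correctly", {
  # every session a point mass on Inf
  ev <- evidence_from_strategies("P1", function(o, f, r) "Inf")
  pr <- participant_profile(ev)
  expect_equal(pr$f_framing, 0, tolerance = 1e-9)
  expect_equal(pr$f_repetitions, 0, tolerance = 1e-9)
  expect_equal(pr$k_social, 0, tolerance = 1e-9)
  expect_equal(pr$k_nonsocial, 0, tolerance = 1e-9)
  # Inf in non-social, 1-ToM in social
  ev <- evidence_from_strategies("P2", function(o, f, r)
    if (f == "social") "1-ToM" else "Inf")
  pr <- participant_profile(ev)
  expect_equal(pr$f_framing, 1, tolerance = 1e-6)
  expect_equal(pr$k_social, 1, tolerance = 1e-6)
  expect_equal(pr$k_nonsocial, 0, tolerance = 1e-6)
  expect_equal(pr$delta_k, pr$k_social - pr$k_nonsocial)
  expect_equal(pr$delta_f, pr$f_framing - pr$f_repetitions)
})

test_that("profiles respect their bounds and completeness checks", {
  ev <- evidence_from_strategies("P3", function(o, f, r)
    sample(repertoire_models(), 1))
  pr <- participant_profile(ev)
  expect_true(pr$f_framing >= 0 && pr$f_framing <= 1)
  expect_true(pr$k_social >= 0 && pr$k_social <= 3)
  expect_error(participant_profile(ev[ev$opponent != "RB", ]), "missing")
  # excluding the pseudo-random opponent still works
  expect_s3_class(participant_profile(ev[ev$opponent != "RB", ],
                                      include_rb = FALSE), "data.frame")
})

test_that("phenotype_table merges cohort metadata", {
  ev <- rbind(evidence_from_strategies("A", function(o, f, r) "RL"),
              evidence_from_strategies("B", function(o, f, r) "2-ToM"))
  cohort <- data.frame(subject_id = c("A", "B"), group = c("AS", "NT"))
  tab <- phenotype_table(ev, cohort)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$k_social[tab$subject_id == "B"], 2, tolerance = 1e-6)
  expect_true(all(c("group", "delta_f", "delta_k") %in% names(tab)))
})
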