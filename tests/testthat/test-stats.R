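fake_features <- function(n_per_group = 10, sep = 3, seed = 1, p = 4) {
  set.seed(seed)
  g <- rep(c("AS", "NT"), each = n_per_group)
  x <- matrix(rnorm(2 * n_per_group * p), ncol = p)
  x[g == "NT", 1] <- x[g == "NT", 1] + sep
  out <- data.frame(subject_id = sprintf("S%02d", seq_along(g)), group = g)
  for (j in seq_len(p)) out[[paste0("f", j)]] <- x[, j]
  out
}

test_that("separable groups are classified perfectly, null data at chance", {
  feat <- fake_features(sep = 6)
  rep_ <- loo_classify(feat, n_permutations = 60, seed = 2)
  expect_equal(rep_$loo_accuracy, 1.0)
  expect_lt(rep_$p_value, 0.05)
  # permutation null centred near one half
  expect_lt(abs(mean(rep_$null_accuracies) - 0.5), 0.1)
  # no signal: accuracy near chance, p large
  feat0 <- fake_features(sep = 0, seed = 5)
  rep0 <- loo_classify(feat0, n_permutations = 60, seed = 2)
  expect_gt(rep0$p_value, 0.05)
})

test_that("LOO accuracy is invariant to consistent feature scaling", {
  feat <- fake_features(sep = 1.5, seed = 7)
  r1 <- loo_classify(feat, n_permutations = 0, seed = 1)
  feat2 <- feat
  for (j in paste0("f", 1:4)) feat2[[j]] <- feat2[[j]] * 37 + 5
  r2 <- loo_classify(feat2, n_permutations = 0, seed = 1)
  expect_equal(r1$loo_accuracy, r2$loo_accuracy)
})

test_that("duplicating every subject cannot hurt held-out accuracy", {
  # under leave-one-out each duplicated subject keeps its twin in the
  # training fold, so accuracy can only move up
  feat <- fake_features(sep = 2, seed = 9, n_per_group = 8)
  dup <- rbind(feat, transform(feat, subject_id = paste0(subject_id, "b")))
  r1 <- loo_classify(feat, n_permutations = 0)
  r2 <- loo_classify(dup, n_permutations = 0)
  expect_gte(r2$loo_accuracy + 1e-9, r1$loo_accuracy)
})

test_that("feature assembly yields 8 performance columns (+4 phenotypes)", {
  spec <- cohort_spec(n_per_group = 2, seed = 21)
  coh <- generate_cohort(spec)
  feat <- assemble_features(coh$sessions, coh$participants)
  perf_cols <- setdiff(names(feat), c("subject_id", "group"))
  expect_length(perf_cols, 8)
  expect_true(all(abs(as.matrix(feat[perf_cols])) <= 1))
  prof <- data.frame(subject_id = coh$participants$subject_id,
                     f_framing = runif(4), f_repetitions = runif(4),
                     k_social = runif(4, 0, 3), k_nonsocial = runif(4, 0, 3))
  feat12 <- assemble_features(coh$sessions, coh$participants, prof,
                              include_phenotypes = TRUE)
  expect_length(setdiff(names(feat12), c("subject_id", "group")), 12)
  # constant columns are dropped with a warning
  prof_const <- prof
  prof_const$k_nonsocial <- 0
  expect_warning(
    feat_dropped <- assemble_features(coh$sessions, coh$participants,
                                      prof_const, include_phenotypes = TRUE),
    "constant")
  expect_false("k_nonsocial" %in% names(feat_dropped))
})

test_that("ridge IRLS agrees with the glmnet reference", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  x <- matrix(rnorm(200), ncol = 4)
  y <- rbinom(50, 1, plogis(0.5 + x %*% c(1, -0.5, 0, 0.25)))
  pen <- 2
  b_irls <- ridge_logistic(x, y, penalty = pen)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = pen / length(y), standardize = FALSE,
                      thresh = 1e-12)
  b_glm <- as.numeric(coef(g))
  expect_equal(b_irls, b_glm, tolerance = 5e-3)
})

test_that("symptom regression recovers exact and null structure", {
  set.seed(11)
  n <- 20
  prof <- data.frame(subject_id = sprintf("S%d", 1:n),
                     f_framing = runif(n), f_repetitions = runif(n),
                     k_social = runif(n, 0, 2), k_nonsocial = runif(n, 0, 2))
  prof$delta_f <- prof$f_framing - prof$f_repetitions
  prof$delta_k <- prof$k_social - prof$k_nonsocial
  y <- 5 + 2 * prof$f_framing - 3 * prof$k_social
  # lm warns about the (intended) perfect fit
  r <- suppressWarnings(symptom_regression(prof, y))
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  # pure-noise outcome: F test usually non-significant
  pvals <- replicate(20, {
    symptom_regression(prof, rnorm(n))$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.8)
  # rank-deficient design names the collinear column
  prof_bad <- prof
  prof_bad$k_nonsocial <- prof_bad$k_social
  expect_error(symptom_regression(prof_bad, y), "collinear")
  expect_error(symptom_regression(prof[1:4, ], y[1:4]), "group size")
})
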