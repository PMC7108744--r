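#' Assemble the per-subject feature table
#'
#' Eight performance features (net correct rate per opponent x framing,
#' averaged over repetitions) and optionally the four computational
#' phenotypes (`f_framing`, `f_repetitions`, `k_social`, `k_nonsocial`).
#' Features are NOT scaled here; [loo_classify()] z-scores within each
#' training fold.  Constant columns are dropped with a warning.
#'
#' @param sessions Stacked session records for the cohort.
#' @param cohort Cohort metadata (`subject_id`, `group`).
#' @param profiles Phenotype table from [phenotype_table()]; required when
#'   `include_phenotypes = TRUE`.
#' @param include_phenotypes Add the four phenotype columns.
#' @return A data frame: `subject_id`, `group`, then feature columns.
#' @export
assemble_features <- function(sessions, cohort, profiles = NULL,
                              include_phenotypes = FALSE) {
  perf <- list()
  for (o in OPPONENT_LEVELS) for (f in FRAMING_LEVELS) {
    sel <- sessions$opponent == o & sessions$framing == f
    agg <- tapply(sessions$reward[sel], sessions$subject_id[sel],
                  function(r) mean(r == 1) - mean(r == 0))
    perf[[paste0("nr_", gsub("-", "", o), "_", gsub("-", "", f))]] <- agg
  }
  feat <- data.frame(subject_id = names(perf[[1]]), stringsAsFactors = FALSE)
  for (nm in names(perf)) feat[[nm]] <- as.numeric(perf[[nm]][feat$subject_id])
  if (include_phenotypes) {
    if (is.null(profiles)) stop("profiles required when include_phenotypes = TRUE")
    feat <- merge(feat, profiles[c("subject_id", "f_framing", "f_repetitions",
                                   "k_social", "k_nonsocial")], by = "subject_id")
  }
  feat <- merge(cohort[c("subject_id", "group")], feat, by = "subject_id")
  if (anyNA(feat)) stop("missing subject data in feature assembly")
  num <- setdiff(names(feat), c("subject_id", "group"))
  const <- num[vapply(feat[num], function(x) sd(x) < 1e-12, logical(1))]
  if (length(const)) {
    warning("dropping constant feature column(s): ", paste(const, collapse = ", "))
    feat <- feat[setdiff(names(feat), const)]
  }
  feat
}

#' Ridge-penalized logistic regression (Newton/IRLS)
#'
#' Minimizes `-loglik + penalty/2 * ||w||^2` with an unpenalized
#' intercept.  Matches `glmnet(alpha = 0, lambda = penalty / n)` on
#' well-conditioned data, but also handles the degenerate folds a
#' leave-one-out loop produces on very small cohorts (single-observation
#' classes, perfect separation), and is fast enough to refit ~10^5 times
#' inside the permutation test.
#'
#' @param x Numeric predictor matrix (no intercept column).
#' @param y01 0/1 outcome vector.
#' @param penalty Ridge penalty on the slopes (absolute, not per-case).
#' @param maxit,tol Newton iteration controls.
#' @return Coefficient vector (intercept first).
#' @export
ridge_logistic <- function(x, y01, penalty = 1, maxit = 100, tol = 1e-9) {
  X <- cbind(1, as.matrix(x))
  p <- ncol(X)
  pen <- c(0, rep(penalty, p - 1))
  b <- numeric(p)
  for (it in seq_len(maxit)) {
    mu <- plogis(drop(X %*% b))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X, y01 - mu) - pen * b
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- drop(solve(H, g))
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

ridge_loo_accuracy <- function(x, y, lambda) {
  n <- length(y)
  correct <- logical(n)
  pred_prob <- numeric(n)
  y01 <- as.integer(y == levels(y)[2])
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y01[-i]
    if (length(unique(ytr)) < 2) stop("a training fold contains a single class")
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv < 1e-12] <- 1
    xtr_s <- scale(xtr, center = mu, scale = sdv)
    xte_s <- (x[i, ] - mu) / sdv
    b <- ridge_logistic(xtr_s, ytr, penalty = lambda * nrow(xtr_s))
    p <- plogis(sum(c(1, xte_s) * b))
    pred_prob[i] <- p
    correct[i] <- (p > 0.5) == (y01[i] == 1)
  }
  list(accuracy = mean(correct), correct = correct, pred_prob = pred_prob)
}

#' Leave-one-out logistic classification of group
#'
#' For each subject, an L2-regularized logistic regression is trained on
#' the remaining subjects (features z-scored on the training fold only) and
#' the held-out label predicted.  Chance level is assessed by re-running
#' the whole LOO loop on label permutations.
#'
#' @param features Feature table from [assemble_features()].
#' @param lambda Fixed ridge penalty (default `1 / n`, the C = 1
#'   equivalent at unit-variance features).
#' @param n_permutations Label permutations for the chance test.
#' @param seed Seed for the permutations.
#' @return A `classification_report` list: `loo_accuracy`, per-subject
#'   held-out predictions, `p_value` (permutation tail probability with the
#'   add-one correction), `n_permutations`, `null_accuracies`.
#' @export
loo_classify <- function(features, lambda = NULL, n_permutations = 1000,
                         seed = 1) {
  y <- factor(features$group)
  if (nlevels(y) != 2) stop("group must have exactly two levels")
  if (min(table(y)) < 2) stop("need at least 2 subjects per group")
  x <- as.matrix(features[setdiff(names(features), c("subject_id", "group"))])
  n <- nrow(x)
  if (is.null(lambda)) lambda <- 1 / n
  obs <- ridge_loo_accuracy(x, y, lambda)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_acc <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    null_acc[b] <- tryCatch(ridge_loo_accuracy(x, yp, lambda)$accuracy,
                            error = function(e) NA_real_)
  }
  null_acc <- null_acc[!is.na(null_acc)]
  p_value <- (1 + sum(null_acc >= obs$accuracy)) / (1 + length(null_acc))
  structure(list(loo_accuracy = obs$accuracy,
                 predictions = data.frame(subject_id = features$subject_id,
                                          group = features$group,
                                          pred_prob = obs$pred_prob,
                                          correct = obs$correct,
                                          stringsAsFactors = FALSE),
                 p_value = p_value, n_permutations = length(null_acc),
                 null_accuracies = null_acc, lambda = lambda),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("LOO accuracy: %.3f (chance p = %.4g, %d permutations)\n",
              x$loo_accuracy, x$p_value, x$n_permutations))
  invisible(x)
}

#' Phenotype-to-symptom regression
#'
#' Ordinary least squares of a symptom score on the four computational
#' phenotypes, with univariate follow-ups on the phenotype deltas
#' (one-sided tests for a negative slope).
#'
#' @param profiles Phenotype table for one group (needs `f_framing`,
#'   `f_repetitions`, `k_social`, `k_nonsocial`, `delta_f`, `delta_k`).
#' @param symptom Numeric symptom scores aligned with `profiles`, or the
#'   name of a column of `profiles`.
#' @return A `symptom_regression` list: `r_squared`, `f_statistic`, `df`,
#'   `p_value`, `coefficients`, and `univariate` (slope, one-sided p for
#'   `delta_k` and `delta_f`).
#' @export
symptom_regression <- function(profiles, symptom = "symptom_social") {
  if (is.character(symptom) && length(symptom) == 1)
    symptom <- profiles[[symptom]]
  stopifnot(length(symptom) == nrow(profiles))
  pred <- c("f_framing", "f_repetitions", "k_social", "k_nonsocial")
  if (nrow(profiles) <= length(pred) + 1)
    stop("group size must exceed number of predictors + 1")
  x <- as.matrix(profiles[pred])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    drop <- pred[qrx$pivot[-seq_len(qrx$rank)] - 1]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  dat <- data.frame(symptom = symptom, profiles[pred])
  fit <- lm(symptom ~ f_framing + f_repetitions + k_social + k_nonsocial,
            data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  uni <- lapply(c(delta_k = "delta_k", delta_f = "delta_f"), function(v) {
    ufit <- lm(symptom ~ x, data = data.frame(symptom = symptom,
                                              x = profiles[[v]]))
    usm <- summary(ufit)$coefficients
    tval <- usm["x", "t value"]
    list(slope = unname(usm["x", "Estimate"]),
         t = unname(tval),
         p_one_sided = unname(pt(tval, df = ufit$df.residual)))
  })
  structure(list(r_squared = sm$r.squared,
                 f_statistic = unname(fstat[1]),
                 df = unname(fstat[2:3]),
                 p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE)),
                 coefficients = coef(fit),
                 univariate = uni, n = nrow(profiles)),
            class = "symptom_regression")
}

#' @export
print.symptom_regression <- function(x, ...) {
  cat(sprintf("R^2 = %.3f, F(%d,%d) = %.2f, p = %.4g\n", x$r_squared,
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("  delta_k slope %.3f (one-sided p = %.3g); delta_f slope %.3f (one-sided p = %.3g)\n",
              x$univariate$delta_k$slope, x$univariate$delta_k$p_one_sided,
              x$univariate$delta_f$slope, x$univariate$delta_f$p_one_sided))
  invisible(x)
}
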