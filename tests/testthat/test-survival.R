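# Survival suite: Kaplan-Meier, log-rank, Cox, BH-FDR, ROC, scan.

test_that("km_estimate matches hand product-limit values and trivial cases", {
  # no censoring: empirical survival
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # censoring reduces the risk set without a step
  km2 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km2$time, c(1, 3, 4))
  expect_equal(km2$surv, c(0.75, 0.375, 0))
  # all censored: S identically 1 (no rows, evaluates to 1 everywhere)
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km3), 0)
  expect_equal(km_surv_at(km3, c(0, 5)), c(1, 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("km with no censoring equals the empirical survival function", {
  set.seed(301)
  for (i in 1:5) {
    t <- sample(1:40, 25, replace = TRUE)
    km <- km_estimate(t, rep(1, 25))
    ecdf_surv <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
    expect_equal(km$surv, ecdf_surv)
  }
})

test_that("logrank_test: symmetry, hand oracle, and transform invariance", {
  # identical event-time multisets in the two groups: O = E by symmetry
  t <- c(1, 2, 3, 1, 2, 3); e <- rep(1, 6); g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, 0)
  expect_equal(unname(lr$hr), 1)
  # 10-subject fixture against the explicit tabulation oracle
  t10 <- c(3, 5, 7, 2, 8, 1, 4, 6, 9, 10)
  e10 <- c(1, 0, 1, 1, 1, 0, 1, 1, 0, 1)
  g10 <- rep(c("a", "b"), 5)
  lr10 <- logrank_test(t10, e10, g10)
  expect_equal(lr10$chisq, logrank_chisq_oracle(t10, e10, g10),
               tolerance = 1e-12)
  # swapping group labels inverts the HR, p unchanged
  g_swap <- ifelse(g10 == "a", "b", "a")
  lr_swap <- logrank_test(t10, e10, g_swap)
  expect_equal(unname(lr_swap$hr), 1 / unname(lr10$hr))
  expect_equal(lr_swap$p_value, lr10$p_value)
  # invariance under strictly increasing time transforms
  lr_tr <- logrank_test(exp(t10), e10, g10)
  expect_equal(lr_tr$chisq, lr10$chisq)
  expect_error(logrank_test(t10, rep(0, 10), g10), "event")
  expect_error(logrank_test(t10, e10, rep("a", 10)), "groups")
})

test_that("logrank_test agrees with survival::survdiff on random data", {
  skip_if_not_installed("survival")
  set.seed(302)
  for (i in 1:4) {
    n <- 80
    t <- round(rexp(n, 0.2), 1); e <- rbinom(n, 1, 0.7)
    g <- sample(c("x", "y"), n, replace = TRUE)
    lr <- logrank_test(t, e, g)
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
  }
  # three groups
  t <- round(rexp(90, 0.2), 1); e <- rbinom(90, 1, 0.7)
  g <- sample(c("x", "y", "z"), 90, replace = TRUE)
  lr3 <- logrank_test(t, e, g)
  sd3 <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr3$df, 2)
  expect_equal(lr3$chisq, sd3$chisq, tolerance = 1e-10)
})

test_that("cox_univariate matches the brute-force partial-likelihood oracle", {
  # 8 subjects, no ties
  t8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e8 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x8 <- c(0.5, -1.2, 0.3, 2.1, -0.7, 1.5, -0.2, 0.9)
  fit <- cox_univariate(t8, e8, x8)
  expect_true(fit$converged)
  expect_equal(fit$beta, cox_beta_oracle(t8, e8, x8), tolerance = 1e-4)
})

test_that("cox_univariate agrees with survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  set.seed(303)
  for (i in 1:4) {
    n <- 120
    t <- round(rexp(n, 0.1), 1)  # induces ties
    e <- rbinom(n, 1, 0.6)
    x <- if (i %% 2) rnorm(n) else rbinom(n, 1, 0.3)
    for (ties in c("efron", "breslow")) {
      fit <- cox_univariate(t, e, x, ties = ties)
      ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = ties)
      expect_equal(fit$beta, unname(stats::coef(ref)), tolerance = 1e-6)
      expect_equal(fit$se, sqrt(unname(stats::vcov(ref)[1, 1])),
                   tolerance = 1e-6)
    }
  }
})

test_that("cox_univariate flags monotone likelihood and rejects bad input", {
  # binary covariate separating all events from all censored subjects
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  e <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- cox_univariate(t, e, x)
  expect_false(fit$converged)
  expect_true(is.na(fit$beta))
  expect_error(cox_univariate(t, e, rep(1, 8)), "constant")
})

test_that("cox beta is invariant under affine time rescaling and null-calibrated", {
  set.seed(304)
  n <- 100
  t <- rexp(n); e <- rbinom(n, 1, 0.7); x <- rnorm(n)
  f1 <- cox_univariate(t, e, x)
  f2 <- cox_univariate(10 * t + 3, e, x)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  # permuted covariate: beta near zero, p roughly uniform
  ps <- replicate(30, {
    fp <- cox_univariate(t, e, sample(x))
    fp$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bh_fdr matches step-up arithmetic, p.adjust and the naive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(305)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_equal(q, stats::p.adjust(p, "BH"))
  expect_equal(q, bh_oracle(p))
  expect_true(all(q >= p))
  # NA propagation and input validation
  expect_equal(bh_fdr(c(0.5, NA))[2], NA_real_)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("roc_auc: trivial cases and all-pairs oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(306)
  m <- sample(1:20, 40, replace = TRUE)  # ties present
  y <- rbinom(40, 1, 0.4)
  expect_equal(roc_auc(m, y), auc_pairs_oracle(m, y))
  expect_error(roc_auc(m, rep(1, 40)), "both outcome classes")
})

test_that("chromosome_scan handles duplicates, skips, and no-loss input", {
  set.seed(307)
  n <- 80
  clin <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     time = rexp(n), event = rbinom(n, 1, 0.7))
  loss <- matrix(0L, n, 4,
                 dimnames = list(clin$sample_id, paste0("g", 1:4)))
  loss[sample(n, 20), "g1"] <- -1L
  loss[, "g2"] <- loss[, "g1"]     # identical column
  loss[sample(n, 15), "g3"] <- -1L
  # g4 has zero carriers: skipped
  res <- chromosome_scan(loss, clin)
  expect_equal(res$p[1], res$p[2])
  expect_equal(res$q[1], res$q[2])
  expect_true(res$skipped[4])
  expect_true(is.na(res$q[4]))
  # no loss anywhere: everything skipped
  res0 <- chromosome_scan(matrix(0L, n, 2,
                                 dimnames = list(clin$sample_id,
                                                 c("a", "b"))), clin)
  expect_true(all(res0$skipped))
})
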