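g3 <- c(0.1, 0.5, 0.9)
v3 <- rep(0.04, 3)

test_that("moment estimators match hand-evaluated closed forms", {
  # Q = 8, k - 1 = 2, DL denominator 50; HS: (8 - 3) / 75
  expect_equal(tau2_dl(g3, v3), 0.12, tolerance = 1e-12)
  expect_equal(tau2_hs(g3, v3), 5 / 75, tolerance = 1e-12)
  # k = 2 direct evaluation: w = 25 each, Q = 0.5, (0.5 - 2)/50 truncates to 0
  expect_equal(tau2_hs(c(0, 0.2), c(0.04, 0.04)),
               max(0, (sum(25 * (c(0, 0.2) - 0.1)^2) - 2) / 50),
               tolerance = 1e-12)
  expect_equal(tau2_hs(c(0, 0.9), c(0.04, 0.04)),
               max(0, (sum(25 * (c(0, 0.9) - 0.45)^2) - 2) / 50),
               tolerance = 1e-12)
  expect_equal(tau2_dl(rep(0.4, 6), runif(6, 0.01, 0.1)), 0)
  expect_equal(tau2_hs(rep(0.4, 4), rep(0.02, 4)), 0)
  # literal general moment form vs Q-form on random samples
  set.seed(61)
  for (i in 1:100) {
    s <- random_meta_sample(sample(3:12, 1))
    expect_equal(tau2_dl(s$g, s$v),
                 oracle_moment_tau2(s$g, s$v, 1 / s$v),
                 tolerance = 1e-12)
    expect_equal(tau2_dl(s$g, s$v), oracle_dl_qform(s$g, s$v),
                 tolerance = 1e-12)
  }
})

test_that("Paule-Mandel solves the generalized Q equation", {
  # equal variances: closed form sum(dev^2)/(k-1) - v
  expect_equal(tau2_pm(g3, v3)$tau2, 0.32 / 2 - 0.04, tolerance = 1e-8)
  expect_equal(tau2_pm(rep(0.3, 5), rep(0.02, 5))$tau2, 0)
  set.seed(62)
  for (i in 1:20) {
    s <- random_meta_sample(5)
    fit <- tau2_pm(s$g, s$v)
    expect_true(fit$converged)
    if (fit$tau2 > 0) {
      expect_lt(abs(oracle_gen_q(fit$tau2, s$g, s$v) - 4), 1e-8)
    } else {
      expect_lte(oracle_gen_q(0, s$g, s$v), 4)
    }
  }
})

test_that("ML and REML fixed points maximize their likelihoods", {
  # equal-variance closed forms: ML mean squared deviation - v, REML the
  # unbiased between-study variance - v
  expect_equal(tau2_ml(g3, v3)$tau2, 0.32 / 3 - 0.04, tolerance = 1e-6)
  expect_equal(tau2_reml(g3, v3)$tau2, 0.32 / 2 - 0.04, tolerance = 1e-6)
  expect_equal(tau2_ml(rep(0.1, 4), rep(0.05, 4))$tau2, 0)
  expect_equal(tau2_reml(rep(0.1, 4), rep(0.05, 4))$tau2, 0)
  set.seed(63)
  for (i in 1:50) {
    s <- random_meta_sample(sample(3:10, 1))
    ml <- tau2_ml(s$g, s$v)
    reml <- tau2_reml(s$g, s$v)
    expect_true(ml$converged)
    expect_true(reml$converged)
    expect_lt(abs(ml$tau2 -
                  oracle_grid_max(s$g, s$v, oracle_ml_loglik)), 1e-4)
    expect_lt(abs(reml$tau2 -
                  oracle_grid_max(s$g, s$v, oracle_reml_loglik)), 1e-4)
  }
})

test_that("estimators agree with the reference implementation", {
  set.seed(64)
  for (i in 1:10) {
    s <- random_meta_sample(sample(4:20, 1))
    for (m in c("DL", "HS", "ML", "PM", "REML")) {
      ref <- metafor::rma(yi = s$g, vi = s$v, method = m,
                          control = list(tol = 1e-10, maxiter = 500))
      mine <- estimate_tau2(s$g, s$v, m)
      # metafor's own stopping rule leaves ~1e-5 slack on ML/REML solutions
      # (the grid-search oracle above adjudicates the exact optimum)
      expect_lt(abs(mine$tau2 - ref$tau2), 1e-4)
    }
  }
})

test_that("equal-variance closed forms hold for DL, PM, REML to 1e-10", {
  set.seed(65)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    v <- runif(1, 0.01, 0.1)
    g <- rnorm(k, 0.2, 0.4)
    closed <- max(0, sum((g - mean(g))^2) / (k - 1) - v)
    expect_equal(tau2_dl(g, rep(v, k)), closed, tolerance = 1e-10)
    expect_equal(tau2_pm(g, rep(v, k))$tau2, closed, tolerance = 1e-8)
    expect_equal(tau2_reml(g, rep(v, k), tol = 1e-12)$tau2, closed,
                 tolerance = 1e-6)
  }
})

test_that("pooling uses inverse random-effects-variance weights", {
  fit <- pool_effect(c(0, 1), c(0.01, 0.99), 0)
  expect_equal(fit$w, c(100, 1 / 0.99))
  expect_equal(fit$theta_hat, (1 / 0.99) / (100 + 1 / 0.99))
  # equal weights reduce to the unweighted mean
  expect_equal(pool_effect(g3, v3, 0.3)$theta_hat, mean(g3))
  expect_error(pool_effect(0.2, 0.04, 0), "k = 2")
})

test_that("Knapp-Hartung inference matches direct formula evaluation", {
  t2 <- tau2_dl(g3, v3)
  kh <- kh_inference(g3, v3, t2)
  w <- 1 / (v3 + t2)
  th <- sum(w * g3) / sum(w)
  se <- sqrt(sum(w * (g3 - th)^2) / (2 * sum(w)))
  expect_equal(kh$theta_hat, th)
  expect_equal(kh$se, se)
  expect_equal(kh$p, 2 * pt(-abs(th / se), 2))
  expect_equal(kh$ci, th + c(-1, 1) * qt(0.975, 2) * se)
  # reference implementation agreement (no truncation of the adjustment)
  ref <- metafor::rma(yi = g3, vi = v3, method = "DL", test = "knha")
  expect_equal(kh$se, ref$se, tolerance = 1e-10)
  expect_equal(kh$p, ref$pval, tolerance = 1e-10)
  # zero-dispersion sample at zero effect
  kh0 <- kh_inference(rep(0, 4), rep(0.05, 4), 0)
  expect_equal(kh0$p, 1)
  expect_equal(kh0$se, 0)
})

test_that("Q-profile bounds solve the chi-square quantile equations", {
  ci <- tau_ci(g3, v3)
  expect_lt(abs(oracle_gen_q(ci[1]^2, g3, v3) - qchisq(0.975, 2)), 1e-6)
  expect_lt(abs(oracle_gen_q(ci[2]^2, g3, v3) - qchisq(0.025, 2)), 1e-6)
  expect_equal(tau_ci(rep(0.3, 5), rep(0.04, 5))[1], 0)
  set.seed(66)
  s <- random_meta_sample(8)
  ci <- tau_ci(s$g, s$v)
  ref <- confint(metafor::rma(yi = s$g, vi = s$v, method = "REML"))
  expect_equal(ci[1], ref$random["tau", "ci.lb"], tolerance = 1e-4)
  expect_equal(ci[2], ref$random["tau", "ci.ub"], tolerance = 1e-4)
})

test_that("I-squared translates Q with truncation at zero", {
  expect_equal(i_squared(g3, v3), 75)  # Q = 8, k = 3
  expect_equal(i_squared(c(0.1, 0.12, 0.11), rep(0.5, 3)), 0)
  expect_equal(i_squared(rep(0.2, 3), rep(0.04, 3)), 0)
})

test_that("all estimators truncate at zero and stay within the effect hull", {
  set.seed(67)
  for (i in 1:20) {
    s <- random_meta_sample(sample(3:10, 1), tau = 0)
    fit <- rema(s$g, s$v, sample(c("DL", "HS", "ML", "PM", "REML"), 1))
    expect_gte(fit$tau2_hat, 0)
    expect_gte(fit$theta_hat, min(s$g))
    expect_lte(fit$theta_hat, max(s$g))
    expect_true(fit$i_squared >= 0 && fit$i_squared <= 100)
  }
})

test_that("study tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(effect = g3, variance = v3, n1 = c(20, 30, 40),
                    n2 = c(20, 30, 40))
  write_study_table(tab, path)
  back <- read_study_table(path)
  expect_equal(back$effect, g3)
  expect_equal(back$variance, v3)
  fit <- rema(back$effect, back$variance, "REML")
  expect_equal(fit$tau2_hat, 0.12, tolerance = 1e-6)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1:3), bad, row.names = FALSE)
  expect_error(read_study_table(bad), "effect")
})
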