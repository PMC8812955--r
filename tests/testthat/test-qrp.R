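test_that("researcher archetypes and environment mixtures are as defined", {
  none <- researcher_profile("none")
  expect_false(any(unlist(none[2:5])))
  ds <- researcher_profile("dv+stop")
  expect_true(ds$uses_optional_dvs && ds$uses_optional_stopping)
  expect_false(ds$uses_optional_moderators || ds$uses_optional_outliers)
  all4 <- researcher_profile("all-four")
  expect_true(all(unlist(all4[2:5])))
  expect_equal(hacking_environment("none")$weights, c(1, 0, 0))
  expect_equal(hacking_environment("medium")$weights, c(0.30, 0.50, 0.20))
  expect_equal(hacking_environment("high")$weights, c(0.10, 0.40, 0.50))
  # mixture frequencies within 3 binomial SEs over 10,000 researchers
  set.seed(41)
  for (lab in c("medium", "high")) {
    env <- hacking_environment(lab)
    draws <- replicate(10000, draw_researcher(env)$archetype)
    freq <- table(factor(draws, levels = env$archetypes)) / 10000
    se <- sqrt(env$weights * (1 - env$weights) / 10000)
    expect_true(all(abs(freq - env$weights) <= 3 * pmax(se, 1e-6)))
  }
})

test_that("analysis enumeration crosses the licensed researcher choices", {
  set.seed(42)
  tb <- simulate_participants(0.2, 60)
  expect_length(enumerate_analyses(tb, researcher_profile("all-four")), 12)
  a1 <- enumerate_analyses(tb, researcher_profile("none"))
  expect_length(a1, 1)
  expect_identical(a1[[1]]$dv, "dv1")
  expect_identical(a1[[1]]$subset, "all")
  expect_false(a1[[1]]$outliers_removed)
  expect_length(enumerate_analyses(tb, researcher_profile("dv+stop")), 2)
  # subsets with < 2 per group are dropped: make an almost-single-sex study
  tb2 <- simulate_participants(0.2, 8)
  tb2$sex <- c("F", "M", "M", "M", "M", "M", "M", "M")
  an <- enumerate_analyses(tb2, researcher_profile("all-four"))
  expect_false(any(vapply(an, `[[`, character(1), "subset") == "F"))
})

test_that("outlier removal drops only |z| >= 2 within the group", {
  # direct z computation: with n = 4 the sample z of 10 is only 1.506, and
  # indeed no 4-value group can reach |z| >= 2 (the maximum is (n-1)/sqrt(n))
  expect_equal(remove_outliers(c(0, 0.1, -0.1, 10)), c(0, 0.1, -0.1, 10))
  # with six values the z of 10 is 2.045 (hand computation) and it is dropped
  x6 <- c(0, 0, 0.1, -0.1, 0.2, 10)
  expect_equal(remove_outliers(x6), c(0, 0, 0.1, -0.1, 0.2))
  expect_equal(remove_outliers(rep(3, 5)), rep(3, 5))  # zero SD: no finite z
  x <- c(-1, -0.5, 0, 0.5, 1)
  expect_equal(remove_outliers(x), x)  # all within 2 SD: unchanged
  # single pass only: the second-largest value is not re-tested after removal
  expect_equal(remove_outliers(remove_outliers(x6)), c(0, 0, 0.1, -0.1, 0.2))
})

test_that("the modified p-value penalizes wrong-direction results", {
  expect_equal(modified_p(0.04, -1, "one"), 1.96)
  expect_equal(modified_p(0.04, 1, "one"), 0.04)
  expect_equal(modified_p(0.04, -1, "two"), 0.04)
  expect_equal(modified_p(0.5, 1, "two"), 0.5)
})

test_that("stopping rules cap collection at 5x start or 200", {
  r <- stopping_rule(100)
  expect_equal(r$increment, 10L)
  expect_equal(r$max_n, 200L)
  expect_equal(stopping_rule(20)$max_n, 100L)
  expect_equal(stopping_rule(20)$increment, 2L)
  # starting sizes above the cap cannot extend
  expect_equal(stopping_rule(244)$max_n, 244L)
})

test_that("a none-profile hacked study is seed-identical to a plain study", {
  for (s in c(7, 19, 53)) {
    set.seed(s)
    r1 <- run_hacked_study(0.3, researcher_profile("none"), stopping_rule(50),
                           "two")
    set.seed(s)
    tb <- simulate_participants(0.3, 50)
    r2 <- analyze_two_groups(tb$dv1[tb$group == 1], tb$dv1[tb$group == 2])
    expect_identical(r1$g, r2$g)
    expect_identical(r1$v, r2$v)
    expect_identical(r1$p, r2$p)
    expect_equal(r1$peek_index, 1L)
  }
})

test_that("optional stopping peeks on the 10% grid and respects the cap", {
  set.seed(43)
  ns <- replicate(300, {
    r <- run_hacked_study(0, researcher_profile("dv+stop"), stopping_rule(100),
                          "two")
    r$n_collected
  })
  expect_true(all(ns %in% seq(100, 200, by = 10)))
  expect_true(any(ns == 200))  # some null studies never stop early
  expect_true(any(ns == 100))  # some stop at the first peek
})

test_that("p-hacking inflates the significance rate far above nominal", {
  set.seed(44)
  sig <- replicate(1500, {
    r <- run_hacked_study(0, researcher_profile("all-four"),
                          stopping_rule(100), "two")
    r$p < 0.05
  })
  expect_gt(mean(sig), 0.15)  # nominal rate would be 5%
})

test_that("published effects inflate monotonically with hacking severity", {
  set.seed(45)
  sm <- sample_size_model()
  reg <- bias_regime("none")
  mean_g <- vapply(c("none", "medium", "high"), function(h) {
    mean(replicate(150, {
      mean(sample_published_literature(9, 0, 0, hacking_environment(h),
                                       reg, sm)$g)
    }))
  }, numeric(1))
  expect_true(mean_g[["none"]] < mean_g[["medium"]])
  expect_true(mean_g[["medium"]] < mean_g[["high"]])
  # reported sizes stay within the stopping bounds
  set.seed(46)
  lit <- sample_published_literature(30, 0, 0, hacking_environment("high"),
                                     reg, sm)
  expect_true(all(lit$n >= 4))
  expect_true(all(lit$n_collected <= 244))
})
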