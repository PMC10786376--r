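test_that("group and study constructors validate", {
  expect_error(group_summary("a", 1, 1), "sample size")
  expect_error(group_summary("a", 5, 0), "variance")
  expect_error(group_summary("", 5, 1), "label")
  g <- group_summary("a", 5, 1)
  expect_error(study_summary(g, list()), "k >= 1")
  expect_error(study_summary(g, list(group_summary("a", 4, 2))), "unique")
  st <- study_summary(g, group_summary("b", 4, 2))
  expect_identical(st$k, 1L)
})

test_that("observed statistic is the control-to-minimum variance ratio", {
  # printed variance columns of the two bundled examples
  t4 <- study_summary(
    group_summary("c", 10, 0.0520),
    list(group_summary("t1", 10, 0.0389), group_summary("t2", 10, 0.0250),
         group_summary("t3", 10, 0.0075)))
  expect_equal(observed_statistic(t4), 0.0520 / 0.0075, tolerance = 1e-12)
  t5 <- study_summary(
    group_summary("c", 6, 0.8841),
    list(group_summary("A", 4, 0.8165), group_summary("B", 5, 2.4240)))
  expect_equal(observed_statistic(t5), 0.8841 / 0.8165, tolerance = 1e-12)
  same <- study_summary(
    group_summary("c", 5, 3), list(group_summary("t", 7, 3)))
  expect_equal(observed_statistic(same), 1)
})

test_that("worked example 1: testosterone variability of smokers", {
  st <- testosterone_study()
  expect_equal(mim_plausibility(st, 1), 0.0117, tolerance = 5e-3)
  expect_equal(round(mim_plausibility(st, 1), 4), 0.0117)
  res <- mim_test(st, alpha = 0.05)
  expect_true(res$reject)
  expect_identical(res$method, "MIM")
})

test_that("worked example 2: blood counts with unequal group sizes", {
  st <- blood_counts_study()
  expect_equal(mim_plausibility(st, 1), 0.6804, tolerance = 1e-4)
  expect_false(mim_test(st, alpha = 0.05)$reject)
})

test_that("plausibility limits in theta and huge-statistic direction", {
  st <- blood_counts_study()
  expect_gt(mim_plausibility(st, 1e-9), 1 - 1e-6)
  expect_lt(mim_plausibility(st, 1e9), 1e-6)
  loud <- study_summary(
    group_summary("c", 10, 1000), list(group_summary("t", 10, 0.01)))
  expect_lt(mim_plausibility(loud, 1), 1e-8)
  expect_true(mim_test(loud)$reject)
})

test_that("k = 1 plausibility equals the one-sided F-test p-value", {
  set.seed(42)
  for (rep in 1:20) {
    st <- random_study(k = 1)
    T <- observed_statistic(st)
    pf_val <- pf(T, st$control$n - 1, st$treatments[[1]]$n - 1,
                 lower.tail = FALSE)
    expect_equal(mim_plausibility(st, 1), pf_val, tolerance = 1e-7)
  }
})

test_that("plausibility is scale invariant", {
  st <- testosterone_study()
  scaled <- study_summary(
    group_summary(st$control$label, st$control$n, st$control$s2 * 37.5),
    lapply(st$treatments, function(g)
      group_summary(g$label, g$n, g$s2 * 37.5)))
  expect_equal(observed_statistic(scaled), observed_statistic(st))
  expect_equal(mim_plausibility(scaled, 1), mim_plausibility(st, 1))
  expect_identical(mim_test(scaled)$reject, mim_test(st)$reject)
})

test_that("plausibility curves are monotone and hit the point value", {
  st <- testosterone_study()
  cur <- plausibility_curve(st)
  expect_length(cur$thetas, 400L)
  expect_true(all(diff(cur$pl_values) <= 1e-10))
  expect_true(all(cur$pl_values >= 0 & cur$pl_values <= 1))
  # default grid spans the informative range
  expect_lt(min(cur$pl_values), 0.01)
  expect_gt(max(cur$pl_values), 0.99)
  grid <- c(0.5, 1, 2)
  expect_equal(plausibility_curve(st, grid)$pl_values[2],
               mim_plausibility(st, 1))
  expect_error(plausibility_curve(st, c(2, 1)), "increasing")
  expect_error(plausibility_curve(st, numeric(0)), "increasing")
})

test_that("upper bound inverts the test and respects duality", {
  st4 <- testosterone_study()
  st5 <- blood_counts_study()
  b4 <- mim_upper_bound(st4, 0.05)
  b5 <- mim_upper_bound(st5, 0.05)
  expect_equal(mim_plausibility(st4, b4), 0.05, tolerance = 1e-6)
  expect_equal(mim_plausibility(st5, b5), 0.05, tolerance = 1e-6)
  expect_lt(b4, 1)  # example 1 rejects at 5%
  expect_gt(b5, 1)  # example 2 does not
  set.seed(314)
  for (rep in 1:10) {
    st <- random_study()
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(mim_test(st, alpha)$reject,
                     mim_upper_bound(st, alpha) < 1)
  }
})

test_that("test result invariants and printing", {
  res <- mim_test(testosterone_study(), 0.05)
  expect_identical(res$reject, res$plausibility <= res$alpha)
  expect_output(print(res), "0.0117")
  expect_output(print(testosterone_study()), "Non-smokers")
  expect_error(mim_test(testosterone_study(), 1.2), "alpha")
})
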