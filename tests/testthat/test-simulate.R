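test_that("spec validation", {
  expect_error(simulation_spec(c(5, 1, 5, 5), c(2, 2, 2, 2)), "sizes")
  expect_error(simulation_spec(c(5, 5), c(2, 0)), "positive")
  expect_error(simulation_spec(c(5, 5), c(2, 2, 2)), "positive|values")
  expect_error(simulation_spec(c(5, 5), c(2, 2), reps = 0), "reps")
  expect_error(simulation_spec(c(5, 6, 7), c(2, 2, 2),
                               methods = c("MIM", "Spurrier")),
               "equal treatment sample sizes")
  # the default method set narrows itself for unequal designs
  expect_identical(simulation_spec(c(5, 6, 7), c(2, 2, 2))$methods, "MIM")
})

test_that("replicates are reproducible and order-independent", {
  spec <- simulation_spec(c(5, 6, 7), c(2, 1, 1), reps = 50, seed = 99)
  a <- generate_study(spec, 17)
  b <- generate_study(spec, 17)
  expect_identical(attr(a, "samples"), attr(b, "samples"))
  expect_identical(a$control$s2, b$control$s2)
  expect_false(identical(attr(generate_study(spec, 18), "samples"),
                         attr(a, "samples")))
  expect_error(generate_study(spec, 51), "rep_index")
  # group sizes and labels as specified
  expect_identical(vapply(attr(a, "samples"), length, integer(1)),
                   c(control = 5L, treatment1 = 6L, treatment2 = 7L))
})

test_that("generated control variances follow the scaled chi-square law", {
  spec <- simulation_spec(c(5, 5, 5, 5), c(1, 1, 1, 1), reps = 2000,
                          seed = 1234)
  s2 <- vapply(seq_len(spec$reps), function(r)
    generate_study(spec, r)$control$s2, numeric(1))
  # (n-1) S^2 / sigma^2 ~ chi^2(4)
  ks <- ks.test(4 * s2, pchisq, df = 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("means shift nothing: the tests are location invariant", {
  base <- simulation_spec(c(6, 8, 5), c(2, 1, 2), reps = 400, seed = 5)
  shifted <- simulation_spec(c(6, 8, 5), c(2, 1, 2), means = c(-3, 10, 0.5),
                             reps = 400, seed = 5)
  expect_identical(run_study(base)$rejection_rate,
                   run_study(shifted)$rejection_rate)
})

test_that("run_study reports rates with binomial standard errors", {
  res <- run_study(simulation_spec(c(8, 8, 8), c(2, 2, 2), reps = 1500,
                                   seed = 21))
  expect_identical(res$reps_used, 1500L)
  expect_identical(names(res$rejection_rate), c("MIM", "Spurrier"))
  expect_equal(res$mc_stderr,
               sqrt(res$rejection_rate * (1 - res$rejection_rate) / 1500))
  # null config: both rates should be near alpha (generous 99.7% band)
  band <- 0.05 + c(-3, 3) * sqrt(0.05 * 0.95 / 1500)
  expect_true(all(res$rejection_rate >= band[1] &
                    res$rejection_rate <= band[2]))
  expect_output(print(res), "type-I-error")
})

test_that("MIM and Spurrier decisions agree replicate by replicate", {
  spec <- simulation_spec(c(7, 9, 9, 9), c(2, 1, 2, 1), reps = 150, seed = 3)
  agree <- vapply(seq_len(spec$reps), function(r) {
    st <- generate_study(spec, r)
    mim_test(st, 0.05)$reject == spurrier_from_study(st, 0.05)$reject
  }, logical(1))
  expect_true(all(agree))
})

test_that("power does not drop when a treatment variance moves below the control", {
  # same seed: paired comparison, (2,2,2,1) vs (2,2,1,1) at fixed sizes
  r1 <- run_study(simulation_spec(c(15, 15, 15, 15), c(2, 2, 2, 1),
                                  reps = 3000, seed = 10, methods = "MIM"))
  r2 <- run_study(simulation_spec(c(15, 15, 15, 15), c(2, 2, 1, 1),
                                  reps = 3000, seed = 10, methods = "MIM"))
  se <- sqrt(r1$mc_stderr^2 + r2$mc_stderr^2)
  expect_gt(r2$rejection_rate["MIM"], r1$rejection_rate["MIM"] - 4 * se)
})

test_that("pl_null_distribution is uniform under the null and validates input", {
  expect_error(pl_null_distribution(
    simulation_spec(c(5, 5, 5), c(2, 1, 2), reps = 10)), "null configuration")
  one <- pl_null_distribution(
    simulation_spec(c(4, 4, 4), c(1, 1, 1), reps = 1, seed = 2))
  expect_length(one$pl, 1L)
  expect_true(one$pl >= 0 && one$pl <= 1)
  expect_null(one$ks)
  d <- pl_null_distribution(
    simulation_spec(c(5, 6, 7, 8), c(3, 3, 3, 3), reps = 2000, seed = 6))
  expect_gt(d$ks$p.value, 0.01)
  # batch CDF evaluation agrees with the adaptive route
  spec <- simulation_spec(c(5, 6, 7, 8), c(3, 3, 3, 3), reps = 50, seed = 6)
  stat <- mimvar:::.simulate_statistics(spec)
  dist <- ratio_dist(4, c(5, 6, 7))
  expect_equal(mimvar:::.ratio_cdf_many(dist, stat),
               ratio_cdf(dist, stat), tolerance = 1e-8)
})
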