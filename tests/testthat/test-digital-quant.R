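test_that("effective partition count subtracts fails and expected dimers", {
  expect_equal(effective_partitions(2500, 0, 1.67), 2498.33)
  expect_equal(effective_partitions(2500, 0, 0), 2500)
  expect_equal(effective_partitions(2500, 100, 1.67), 2398.33)
  expect_error(effective_partitions(2500, 2499, 2), "non-positive")
})

test_that("lambda follows the zero-class inversion and flags saturation", {
  expect_equal(lambda_from_positives(0, 2500), 0)
  expect_equal(lambda_from_positives(500, 2500), -log(0.8))
  expect_error(lambda_from_positives(2500, 2500), "saturated")
  expect_error(total_copies_digital(2500, 2500), "saturated")
})

test_that("total copies reproduces the chip's low-concentration table", {
  expect_equal(round(total_copies_digital(3.5, 2500), 2), 3.50)
  expect_equal(round(total_copies_digital(35, 2500), 2), 35.24)
  expect_equal(round(total_copies_digital(2301, 2500), 2), 6325.59)
  # k = 1 is the exact fixed point: one positive well, one copy
  expect_equal(total_copies_digital(1, 2500), 1)
})

test_that("total copies is increasing, convex, >= k, and matches lambda scaling", {
  ks <- seq(1, 2400, by = 7)
  tc <- vapply(ks, total_copies_digital, numeric(1), n_eff = 2500)
  expect_true(all(diff(tc) > 0))
  expect_true(all(diff(diff(tc)) > 0))
  expect_true(all(tc >= ks))
  # exact identity with lambda / (-log(1 - 1/n))
  lam <- vapply(ks, lambda_from_positives, numeric(1), n_eff = 2500)
  expect_equal(tc, lam / (-log(1 - 1 / 2500)))
  # and within 0.03% of the continuous-volume lambda * n approximation
  expect_true(all(abs(tc - lam * 2500) / tc < 3e-4))
})

test_that("per-partition copy pmf is Poisson and sums to one", {
  expect_equal(poisson_copy_pmf(0, 0), 1)
  expect_equal(poisson_copy_pmf(1, 1), exp(-1))
  expect_equal(poisson_copy_pmf(0.2, 2), exp(-0.2) * 0.04 / 2)
  expect_equal(sum(poisson_copy_pmf(2.5, 0:100)), 1)
})

test_that("single-copy probabilities follow both conventions", {
  expect_equal(round(single_copy_probability(454.5, 2500), 1), 98.5)
  expect_equal(round(single_copy_probability(2301, 2500), 1), 76.5)
  # both conventions approach 100% as occupancy vanishes
  expect_equal(single_copy_probability(0.01, 2500), 100, tolerance = 1e-4)
  expect_equal(
    single_copy_probability(0.01, 2500, convention = "exactly_one_given_positive"),
    100, tolerance = 1e-2)
  # conditional convention undefined at k = 0
  expect_error(
    single_copy_probability(0, 2500, convention = "exactly_one_given_positive"),
    "undefined")
  # failed wells shrink the denominator
  expect_gt(single_copy_probability(454.5, 2500),
            single_copy_probability(454.5, 2500, n_fail = 400))
})

test_that("an empty chip quantifies to zero copies", {
  q <- quantify_run(make_run())
  expect_equal(q$total_copies, 0)
  expect_equal(q$lambda_mean, 0)
  expect_equal(q$p_at_most_one, 100)
  expect_true(is.na(q$p_exactly_one))
})

test_that("quantifying a simulated chip recovers the loaded copies", {
  cfg <- sim_config()
  run <- simulate_chip(500, cfg, seed = 42)
  ntc <- simulate_ntc(cfg)
  q <- quantify_run(run, ntc = ntc)
  # truth inside the reported interval, estimate within Poisson-scale error
  expect_gt(500, q$ci_lower)
  expect_lt(500, q$ci_upper)
  expect_lt(abs(q$total_copies - 500) / 500, 0.15)
})

test_that("the copy-number interval covers the truth across replicates", {
  set.seed(202)
  cfg <- sim_config()
  truth <- 100
  covered <- vapply(1:200, function(i) {
    q <- quantify_run(simulate_chip(truth, cfg), ntc = simulate_ntc(cfg))
    q$ci_lower <= truth && truth <= q$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("replicate quantification averages counts before the transform", {
  # two chips with 454 and 455 positives reproduce the mean-k workflow
  r1 <- make_run(rep(26.4, 454))
  r2 <- make_run(rep(26.5, 455))
  q <- quantify_replicates(list(r1, r2))
  expect_equal(q$k_positive, 454.5)
  expect_equal(round(q$total_copies, 2), 501.52)
})
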