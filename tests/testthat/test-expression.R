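test_that("per-cell copies double for every cycle below the reference", {
  expect_equal(copies_per_cell(26.2, 26.2), 1)
  expect_equal(copies_per_cell(16.2, 26.2), 1024)
  expect_equal(copies_per_cell(28.2, 26.2), 0.25)
  cq <- seq(15, 35, by = 0.5)
  expect_true(all(diff(copies_per_cell(cq, 26.2)) < 0))
})

test_that("geometric means equal the Cq-space arithmetic mean", {
  expect_equal(geometric_mean_copies(c(2, 8)), 4)
  expect_equal(geometric_mean_copies(rep(3.7, 10)), 3.7)
  set.seed(1)
  cq <- rnorm(100, 28, 1.5)
  expect_equal(geometric_mean_copies(copies_per_cell(cq, 26.2)),
               copies_per_cell(mean(cq), 26.2))
  expect_error(geometric_mean_copies(numeric(0)), "no reactive wells")
  expect_error(geometric_mean_copies(c(1, -2)), "positive")
})

test_that("one-sample KS p-values are uniform under a known-parameter null", {
  set.seed(2)
  p <- vapply(1:300, function(i) {
    ks_one_sample(rnorm(200, 5, 2), "normal", params = c(5, 2))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("one-sample KS rejects strong bimodality with high power", {
  set.seed(3)
  reject <- vapply(1:40, function(i) {
    x <- c(rnorm(150, -3, 0.5), rnorm(150, 3, 0.5))
    ks_one_sample(x, "normal")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
  # lognormal family = normality on the log scale
  set.seed(4)
  y <- rlnorm(300, 2, 0.7)
  r <- ks_one_sample(y, "lognormal")
  expect_gt(r$p_value, 0.001)
  expect_error(ks_one_sample(c(-1, 1, 2, 3, 4), "lognormal"), "positive")
  expect_error(ks_one_sample(rep(2, 10), "normal"), "degenerate")
})

test_that("the bootstrap p-value accounts for estimated moments", {
  set.seed(5)
  r <- ks_one_sample(rnorm(100), "normal", bootstrap = TRUE, n_boot = 99)
  expect_true(r$p_value_bootstrap > 0 && r$p_value_bootstrap <= 1)
})

test_that("two-sample KS is symmetric and monotone-transform invariant", {
  set.seed(6)
  a <- rlnorm(80, 1, 0.5)
  b <- rlnorm(80, 1.6, 0.5)
  r_ab <- ks_two_sample(a, b)
  r_ba <- ks_two_sample(b, a)
  expect_equal(r_ab$statistic_D, r_ba$statistic_D)
  # D is the same on linear copies and on any monotone rescaling
  r_lin <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(r_ab$statistic_D, unname(r_lin$statistic))
  # identical samples: D = 0; disjoint supports: D = 1
  expect_equal(ks_two_sample(a, a)$statistic_D, 0)
  expect_equal(ks_two_sample(a, a + 100)$statistic_D, 1)
})

test_that("two-sample KS detects a two-fold expression shift", {
  set.seed(7)
  reject <- vapply(1:30, function(i) {
    a <- rlnorm(400, log(20), 0.8)
    b <- rlnorm(400, log(40), 0.8)
    ks_two_sample(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.9)
})

test_that("time-course profiling reports means, histograms and KS matrix", {
  set.seed(8)
  records <- simulate_emt_experiment(emt_scenario(), sim_config(), seed = 8)
  records <- records[records$n_cells_true == 1, ]
  records$copies <- records$copies_observed
  prof <- profile_timecourse(records)
  ncad <- prof$genes[["N-cadherin"]]
  # monotone increase of the geometric means across the time course
  expect_true(all(diff(ncad$geometric_means) > 0))
  expect_equal(nrow(ncad$comparisons), 6)
  expect_true(all(c("p_raw", "p_holm") %in% names(ncad$comparisons)))
  expect_true(all(vapply(ncad$histograms, function(h) sum(h$counts),
                         integer(1)) == ncad$n_per_condition))
  # single condition: means only, no tests
  solo <- profile_timecourse(records[records$condition == "control", ])
  expect_null(solo$genes[["vimentin"]]$comparisons)
  # Cq-only records convert through the reference anchor
  prof2 <- profile_timecourse(records[, c("well_id", "gene", "condition", "cq")],
                              cq1_ref = 26.2)
  expect_equal(prof2$genes[["N-cadherin"]]$geometric_means,
               ncad$geometric_means)
  expect_error(
    profile_timecourse(records[, c("well_id", "gene", "condition", "cq")]),
    "cq1_ref")
})
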