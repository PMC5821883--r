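make_series <- function(mean_cq, conc = 10^seq_along(mean_cq)) {
  dilution_series(Map(function(c0, cq) list(concentration = c0, cq_values = cq),
                      conc, mean_cq))
}

test_that("a perfect-doubling series fits slope -3.3219 and E = 100%", {
  conc <- 10^(1:6)
  s <- make_series(as.list(40 - log2(10) * log10(conc)), conc)
  fit <- fit_standard_curve(s)
  expect_equal(fit$slope, -log2(10), tolerance = 1e-9)
  expect_equal(fit$efficiency_fraction, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 40, tolerance = 1e-9)
})

test_that("efficiency follows 10^(-1/slope) - 1", {
  expect_equal(efficiency_from_slope(-3.59), 10^(1 / 3.59) - 1)
  expect_equal(round(efficiency_from_slope(-3.59), 3), 0.899)
  # two-point line at 10x dilution
  s <- make_series(list(33.3219, 30), c(10, 100))
  fit <- fit_standard_curve(s)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-4)
  expect_equal(fit$efficiency_fraction, 1, tolerance = 1e-3)
  expect_error(fit_standard_curve(make_series(list(20, 21), c(5, 5))),
               "distinct")
})

test_that("digital-regime detection splits plateau from linear levels", {
  # constructed: three lowest levels share a plateau within 0.5 cycles
  s <- make_series(list(26.4, 26.5, 26.6, 23.3, 20))
  reg <- detect_digital_regime(s)
  expect_equal(reg$plateau_levels, 1:3)
  expect_equal(reg$linear_levels, 4:5)
  # strictly linear series has no plateau
  s2 <- make_series(as.list(40 - 3.3 * (1:6)))
  reg2 <- detect_digital_regime(s2)
  expect_length(reg2$plateau_levels, 0)
  expect_equal(reg2$linear_levels, 1:6)
  expect_error(detect_digital_regime(make_series(list(20, 23))), "3 levels")
})

test_that("a simulated 9-level series shows the plateau in the four lowest", {
  sim <- simulate_dilution_series(3.4 * 10^(0:8), sim_config(), bulk = FALSE,
                                  seed = 5)
  reg <- detect_digital_regime(sim$series)
  expect_equal(reg$plateau_levels, 1:4)
  expect_equal(reg$linear_levels, 5:9)
  fit <- fit_standard_curve(sim$series, reg$linear_levels)
  expect_lt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.99)
  # fitted efficiency within 2 points of the generator's truth
  expect_lt(abs(fit$efficiency_percent - 89.81), 2)
})

test_that("single-copy anchoring pools digital-regime wells", {
  r <- make_run(rep(26.2, 40))
  a <- estimate_single_copy_cq(r)
  expect_equal(a$cq1_mean, 26.2)
  expect_equal(a$cq1_sd, 0)
  # per-level weighting averages level means
  r1 <- make_run(rep(26.32, 10))
  r2 <- make_run(rep(26.58, 90))
  a2 <- estimate_single_copy_cq(list(r1, r2), weighting = "per_level")
  expect_equal(a2$cq1_mean, 26.45)
  # per-well weighting pools wells instead
  a3 <- estimate_single_copy_cq(list(r1, r2), weighting = "per_well")
  expect_equal(a3$cq1_mean, 0.1 * 26.32 + 0.9 * 26.58)
  # a saturated run does not qualify for the digital regime
  expect_error(estimate_single_copy_cq(make_run(rep(20, 2400))),
               "no runs qualify")
})

test_that("anchor recovery from simulated digital runs is unbiased", {
  set.seed(314)
  cfg <- sim_config(cq_noise_sd = 0.4, dimer_rate_mean = 0)
  runs <- lapply(c(35, 35, 170), function(tot) simulate_chip(tot, cfg))
  a <- estimate_single_copy_cq(runs)
  sem <- a$cq1_sd / sqrt(a$n_wells)
  expect_lt(abs(a$cq1_mean - cfg$cq1_true), 3 * sem + 1e-9)
})

test_that("copy conversion is anchored, monotone, and exact on examples", {
  a <- structure(list(cq1_mean = 26.2), class = "single_copy_anchor")
  expect_equal(copies_from_cq(26.2, a, 0.9), 1)
  expect_equal(copies_from_cq(25.2, a, 1), 2)
  expect_equal(copies_from_cq(16.2, a, 0.8981), 1.8981^10)
  cq <- seq(10, 40, by = 0.5)
  expect_true(all(diff(copies_from_cq(cq, a, 0.8981)) < 0))
})

test_that("per-level copy estimates track true inputs across the dynamic range", {
  sim <- simulate_dilution_series(3.4 * 10^(0:8), sim_config(), bulk = FALSE,
                                  seed = 9)
  reg <- detect_digital_regime(sim$series)
  anchor_runs <- unlist(lapply(sim$series$levels[reg$plateau_levels],
                               `[[`, "runs"), recursive = FALSE)
  anchor <- estimate_single_copy_cq(anchor_runs)
  lv <- level_means(sim$series)
  # per-level total-copy estimate: digital counting in the plateau,
  # anchored Cq conversion (per positive well) times positives elsewhere
  est <- vapply(seq_along(sim$series$levels), function(i) {
    l <- sim$series$levels[[i]]
    ks <- vapply(l$runs, function(r) status_counts(r)[["positive"]], integer(1))
    if (i %in% reg$plateau_levels) {
      total_copies_digital(mean(ks), 2500)
    } else {
      copies_from_cq(lv$mean_cq[i], anchor, 0.8981) * mean(ks)
    }
  }, numeric(1))
  truth <- lv$concentration * sim_config()$sample_volume_ul
  r2 <- summary(stats::lm(log10(est) ~ log10(truth)))$r.squared
  expect_gte(r2, 0.99)
})
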