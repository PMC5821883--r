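test_that("molecule and cell placements conserve totals", {
  for (tot in c(0, 1, 35, 2500, 170000)) {
    expect_equal(sum(partition_molecules(tot, 2500, seed = tot + 1)), tot)
  }
  l <- simulate_cell_loading(500, seed = 10)
  expect_equal(sum(l$cells_per_well), 500)
  expect_equal(l$observation$n0 + l$observation$n1 + l$observation$n2plus, 2500)
})

test_that("a fixed seed reproduces runs exactly; different seeds differ", {
  a <- simulate_chip(500, seed = 123)
  b <- simulate_chip(500, seed = 123)
  c <- simulate_chip(500, seed = 124)
  expect_identical(a$wells, b$wells)
  expect_false(identical(a$wells$cq, c$wells$cq))
})

test_that("per-well occupancy is Poisson at chip scale", {
  set.seed(20)
  counts <- unlist(lapply(1:10, function(i) {
    simulate_cell_loading(2500)$cells_per_well
  }))
  tab <- tabulate(counts + 1, nbins = 8)  # occupancies 0..7+
  p <- dpois(0:6, 1)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(stats::chisq.test(tab, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("a noiseless low-copy chip shows singleton wells at the anchor Cq", {
  cfg <- sim_config(cq_noise_sd = 0, dimer_rate_mean = 0)
  run <- simulate_chip(35, cfg, seed = 30)
  counts <- status_counts(run)
  expect_true(abs(counts[["positive"]] - 35) <= 1)  # at most one collision
  expect_true(all(abs(run$wells$cq[run$wells$status == "positive"] -
                        cfg$cq1_true) < 0.6))
  # saturating totals light every well well below the anchor
  run_hi <- simulate_chip(1.7e8, cfg, seed = 31)
  expect_equal(status_counts(run_hi)[["positive"]], 2500L)
  expect_lt(mean(run_hi$wells$cq), cfg$cq1_true - 10)
})

test_that("dimer wells carry the NTC signature and only template-free wells", {
  set.seed(40)
  k_ntc <- vapply(1:300, function(i) {
    sum(status_counts(simulate_ntc())[c("positive", "dimer")])
  }, integer(1))
  expect_equal(mean(k_ntc), 1.67, tolerance = 0.15)
  cqs <- unlist(lapply(1:50, function(i) {
    r <- simulate_ntc()
    r$wells$cq[r$wells$status == "dimer"]
  }))
  expect_equal(mean(cqs), 28.8, tolerance = 1.5)
  expect_true(all(cqs <= 40))
})

test_that("noiseless bulk dilution series has the exact theoretical slope", {
  cfg <- sim_config(cq_noise_sd = 0, dimer_rate_mean = 0,
                    sample_volume_ul = 1)
  concs <- 10^(3:7)
  sim <- simulate_dilution_series(concs, cfg, replicates = 1, bulk = TRUE,
                                  seed = 50)
  cq <- vapply(sim$bulk, function(b) mean(b$cq_values), numeric(1))
  slope <- unname(coef(lm(cq ~ log10(concs)))[2])
  # single aliquot, zero noise: the line is exact
  expect_equal(slope, -1 / log10(1 + cfg$efficiency_true), tolerance = 1e-9)
  expect_equal(efficiency_from_slope(slope), cfg$efficiency_true,
               tolerance = 1e-9)
})

test_that("bulk replicates split the template and converge at high copies", {
  b <- simulate_bulk_qpcr(3e6, replicates = 3,
                          config = sim_config(cq_noise_sd = 0), seed = 60)
  expect_length(b$cq_values, 3)
  expect_lt(sd(b$cq_values), 0.01)
  b0 <- simulate_bulk_qpcr(0, replicates = 3, seed = 61)
  expect_true(all(is.na(b0$cq_values)))
})

test_that("an uninhibited chip matches the plain generator seed-for-seed", {
  cfg <- sim_config()
  a <- simulate_chip(800, cfg, seed = 70)
  b <- simulate_inhibited_chip(800, 0, config = cfg, seed = 70)
  expect_identical(a$wells$cq, b$wells$cq)
})

test_that("at the complete-inhibition midpoint about half the wells are lost", {
  set.seed(71)
  params <- inhibition_sim_params(ic50_complete = 0.02, eprime_slope = 0)
  cfg <- sim_config(dimer_rate_mean = 0)
  frac <- vapply(1:20, function(i) {
    nic <- status_counts(simulate_inhibited_chip(1000, 0, params, cfg))
    inh <- status_counts(simulate_inhibited_chip(1000, 0.02, params, cfg))
    inh[["positive"]] / nic[["positive"]]
  }, numeric(1))
  expect_equal(mean(frac), 0.5, tolerance = 0.05)
})

test_that("EMT geometric means are recovered from singlet wells", {
  scen <- emt_scenario()
  records <- simulate_emt_experiment(scen, sim_config(), seed = 80)
  singlets <- records[records$n_cells_true == 1, ]
  for (cond_i in c(1, 4)) {
    cond <- scen$conditions[cond_i]
    sub <- singlets[singlets$gene == "N-cadherin" & singlets$condition == cond, ]
    expect_gt(nrow(sub), 300)
    gm <- geometric_mean_copies(sub$copies_observed)
    truth <- scen$genes[["N-cadherin"]][cond_i]
    expect_lt(abs(gm - truth) / truth, 0.1)
  }
})
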