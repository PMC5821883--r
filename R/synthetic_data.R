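# Seedable generator for every input the pipeline consumes.
#
# The generator emulates the statistical structure the analysis assumes:
# multinomial partitioning of molecules (or cells) into 2,500 wells of
# 20 nL, per-well Cq values anchored at the single-copy Cq with
# amplification-efficiency scaling and Gaussian noise, failed wells,
# primer-dimer false positives in template-free wells, per-well heparin
# inhibition (a mix of complete inhibition and efficiency loss), Poisson
# cell loading, and per-cell lognormal gene expression.
#
# Amplification model: a well with m molecules amplifying at efficiency
# E_w crosses the shared detection threshold K = (1 + E)^Cq1 (one molecule
# at nominal efficiency E) at
#   Cq = (Cq1 ln(1 + E) - ln m) / ln(1 + E_w),
# which reduces to Cq1 - ln(m)/ln(1 + E) when E_w = E. This is the unique
# form consistent with copy conversion by (1 + E)^(Cq1 - Cq).

#' Simulation configuration
#'
#' Defaults reproduce the characterised chip: 2,500 partitions of 20 nL,
#' single-copy Cq 26.20, amplification efficiency 89.81%, per-well Cq noise
#' 0.4 cycles (within the observed per-level SDs of 0.19-0.72), a mean of
#' 1.67 primer-dimer false positives per chip with Cq ~ N(28.80, 5.08)
#' clipped to (0, 40], 40-cycle protocol, and an effective template volume
#' of 0.5 uL per chip for converting concentrations to per-chip copies.
#'
#' @param n_partitions wells per chip
#' @param well_volume_nl well volume, nL (carried for bookkeeping)
#' @param cq1_true true single-copy Cq
#' @param efficiency_true true amplification efficiency (fraction)
#' @param cq_noise_sd per-well Cq noise SD, cycles
#' @param fail_rate per-well probability of an unfilled/bubbled well
#' @param dimer_rate_mean mean primer-dimer false positives per chip
#' @param dimer_cq_mean,dimer_cq_sd Cq distribution of dimer wells
#' @param max_cycles protocol cycle count
#' @param sample_volume_ul effective template volume per chip, uL
#' @return a `sim_config` list
#' @export
sim_config <- function(n_partitions = 2500, well_volume_nl = 20,
                       cq1_true = 26.20, efficiency_true = 0.8981,
                       cq_noise_sd = 0.4, fail_rate = 0,
                       dimer_rate_mean = 1.67, dimer_cq_mean = 28.80,
                       dimer_cq_sd = 5.08, max_cycles = 40,
                       sample_volume_ul = 0.5) {
  stopifnot(fail_rate >= 0, fail_rate <= 1, cq_noise_sd >= 0,
            dimer_rate_mean >= 0, dimer_cq_sd >= 0,
            efficiency_true > 0, n_partitions >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Partition molecules into wells
#'
#' Places each of `total_copies` molecules uniformly at random into one of
#' `n_partitions` wells (multinomial partitioning); marginal per-well
#' counts converge to Poisson(total/n). The counts always sum to the total.
#'
#' @param total_copies number of molecules (integer >= 0)
#' @param n_partitions number of wells
#' @param seed optional integer seed
#' @return integer vector of per-well molecule counts
#' @export
partition_molecules <- function(total_copies, n_partitions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(total_copies >= 0)
  if (total_copies == 0) return(integer(n_partitions))
  as.integer(stats::rmultinom(1, total_copies,
                              rep(1 / n_partitions, n_partitions)))
}

# Cq for wells holding m >= 1 molecules at per-well efficiency e_w,
# anchored at the config's single-copy Cq / nominal efficiency.
amplification_cq <- function(m, config, e_well = config$efficiency_true) {
  (config$cq1_true * log(1 + config$efficiency_true) - log(m)) /
    log(1 + e_well)
}

# place dimer false positives into template-free wells; returns the wells df
add_dimer_wells <- function(wells, config) {
  empty <- which(wells$status == "negative")
  if (length(empty) == 0 || config$dimer_rate_mean <= 0) return(wells)
  n_dimer <- min(stats::rpois(1, config$dimer_rate_mean), length(empty))
  if (n_dimer == 0) return(wells)
  idx <- sample(empty, n_dimer)
  cq <- stats::rnorm(n_dimer, config$dimer_cq_mean, config$dimer_cq_sd)
  cq <- pmin(pmax(cq, 1e-6), config$max_cycles)
  wells$cq[idx] <- cq
  wells$status[idx] <- "dimer"
  wells
}

# core chip synthesis shared by the template and inhibition generators
build_chip <- function(per_well_cq, config, metadata) {
  n <- config$n_partitions
  grid_dim <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  wells <- data.frame(
    well_id = sprintf("R%dC%d", idx %/% grid_dim, idx %% grid_dim),
    row = idx %/% grid_dim, col = idx %% grid_dim,
    cq = per_well_cq,
    status = ifelse(is.na(per_well_cq), "negative", "positive"),
    stringsAsFactors = FALSE)
  # late wells that never cross threshold within the protocol are negative
  over <- !is.na(wells$cq) & wells$cq > config$max_cycles
  wells$cq[over] <- NA_real_
  wells$status[over] <- "negative"
  wells <- add_dimer_wells(wells, config)
  if (config$fail_rate > 0) {
    failed <- stats::runif(n) < config$fail_rate
    wells$status[failed] <- "fail"
  }
  chip_run(wells, n_partitions = n, metadata = metadata)
}

#' Simulate one chip run
#'
#' Partitions `total_copies` molecules into the chip's wells, assigns each
#' occupied well a Cq from the anchored amplification model plus Gaussian
#' noise, leaves empty wells negative, adds primer-dimer false positives in
#' template-free wells, and marks failed wells.
#'
#' @param total_copies molecules loaded on the chip
#' @param config a [sim_config()]
#' @param seed optional integer seed
#' @param metadata metadata list attached to the run
#' @return a `chip_run`
#' @export
simulate_chip <- function(total_copies, config = sim_config(), seed = NULL,
                          metadata = list()) {
  if (!is.null(seed)) set.seed(seed)
  m <- partition_molecules(total_copies, config$n_partitions)
  cq <- rep(NA_real_, config$n_partitions)
  occ <- which(m >= 1)
  if (length(occ) > 0) {
    cq[occ] <- amplification_cq(m[occ], config) +
      stats::rnorm(length(occ), 0, config$cq_noise_sd)
  }
  build_chip(cq, config, metadata)
}

#' Simulate a no-template control chip
#'
#' A chip with zero template: only primer-dimer false positives (and
#' failed wells) appear.
#'
#' @inheritParams simulate_chip
#' @return a `chip_run` with `is_ntc = TRUE` metadata
#' @export
simulate_ntc <- function(config = sim_config(), seed = NULL) {
  simulate_chip(0, config, seed, metadata = list(is_ntc = TRUE))
}

#' Simulate a serial-dilution series
#'
#' One or more chip runs per concentration (copies per chip =
#' concentration x `sample_volume_ul`), plus matched bulk triplicates when
#' requested. The digital plateau emerges below about one copy per
#' partition.
#'
#' @param concentrations copies/uL, any order (returned sorted ascending)
#' @param config a [sim_config()]
#' @param replicates chips (and bulk replicates) per level
#' @param bulk also simulate matched bulk qPCR replicates
#' @param seed optional integer seed
#' @return list with `series` (a [dilution_series()] of per-well positive
#'   Cq values with `runs` attached per level) and `bulk` (list of
#'   `bulk_qpcr` per level, or `NULL`)
#' @export
simulate_dilution_series <- function(concentrations, config = sim_config(),
                                     replicates = 3, bulk = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(concentrations) >= 1)
  concentrations <- sort(concentrations)
  levels <- lapply(concentrations, function(conc) {
    copies <- round(conc * config$sample_volume_ul)
    runs <- lapply(seq_len(replicates), function(i) {
      simulate_chip(copies, config,
                    metadata = list(nominal_concentration = conc))
    })
    cqs <- unlist(lapply(runs, function(r) {
      r$wells$cq[r$wells$status == "positive"]
    }))
    list(concentration = conc, cq_values = cqs, runs = runs)
  })
  bulk_out <- NULL
  if (bulk) {
    bulk_out <- lapply(concentrations, function(conc) {
      # bulk reaction volume matched to the chip's effective template volume
      copies <- round(conc * config$sample_volume_ul)
      simulate_bulk_qpcr(copies, replicates = replicates, config = config)
    })
  }
  list(series = dilution_series(levels), bulk = bulk_out)
}

#' Inhibition simulation parameters
#'
#' Heparin acts through two channels: complete per-well inhibition with a
#' log-logistic dose-response (midpoint `ic50_complete`), and a reduction
#' of amplification efficiency that grows with log concentration
#' (`eprime_slope` per decade, <= 0).
#'
#' @param ic50_complete concentration at which half the wells are fully
#'   inhibited, IU/mL
#' @param hill hill slope of the complete-inhibition dose response
#' @param eprime_slope efficiency decrement per log10 unit of (1 + c/c_ref)
#' @param c_ref reference concentration scaling the efficiency loss, IU/mL
#' @param concentrations default tested final concentrations, IU/mL
#' @return an `inhibition_sim_params` list
#' @export
inhibition_sim_params <- function(ic50_complete = 0.02, hill = 1,
                                  eprime_slope = -0.04, c_ref = 0.001,
                                  concentrations = c(0.001, 0.01, 0.025,
                                                     0.05, 0.25)) {
  stopifnot(ic50_complete > 0, eprime_slope <= 0)
  structure(as.list(environment()), class = "inhibition_sim_params")
}

# probability a well's reaction is completely inhibited at concentration c
complete_inhibition_prob <- function(concentration, params) {
  if (concentration <= 0) return(0)
  1 / (1 + (params$ic50_complete / concentration)^params$hill)
}

# efficiency decrement at concentration c (0 at c = 0, bounded below)
eprime_at <- function(concentration, params, config) {
  ep <- params$eprime_slope * log10(1 + concentration / params$c_ref)
  max(ep, -(config$efficiency_true * 0.9))
}

#' Simulate an inhibited chip run
#'
#' Each well is independently fully inhibited with the log-logistic
#' probability at the given heparin concentration; surviving occupied wells
#' amplify at the reduced efficiency `E + E'(c)`, shifting their Cq upward
#' through the shared-threshold model. Wells pushed past the protocol's
#' cycle count become negative.
#'
#' @param total_copies molecules loaded on the chip
#' @param concentration final heparin concentration, IU/mL
#' @param params an [inhibition_sim_params()]
#' @param config a [sim_config()]
#' @param seed optional integer seed
#' @return a `chip_run` with `inhibitor_concentration` metadata
#' @export
simulate_inhibited_chip <- function(total_copies, concentration,
                                    params = inhibition_sim_params(),
                                    config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- partition_molecules(total_copies, config$n_partitions)
  p_dead <- complete_inhibition_prob(concentration, params)
  eprime <- eprime_at(concentration, params, config)
  e_well <- config$efficiency_true + eprime
  cq <- rep(NA_real_, config$n_partitions)
  occ <- which(m >= 1)
  if (length(occ) > 0) {
    alive <- if (p_dead > 0) occ[stats::runif(length(occ)) >= p_dead] else occ
    if (length(alive) > 0) {
      cq[alive] <- amplification_cq(m[alive], config, e_well = e_well) +
        stats::rnorm(length(alive), 0, config$cq_noise_sd)
    }
  }
  build_chip(cq, config,
             metadata = list(inhibitor_concentration = concentration))
}

#' Simulate bulk qPCR replicates
#'
#' Divides the template into `replicates` equal aliquots (multinomial, so
#' counts are conserved) and reports one Cq per aliquot from the anchored
#' amplification model plus noise; aliquots with zero template report no
#' amplification (`NA`). At non-zero inhibitor concentration the whole
#' reaction amplifies at the reduced efficiency and the completely
#' inhibited template fraction is removed, so bulk reactions take the full
#' efficiency penalty that partitioned chips escape.
#'
#' @param total_copies total template copies across all replicates
#' @param replicates number of replicate reactions (default 3)
#' @param config a [sim_config()]
#' @param concentration final inhibitor concentration, IU/mL (default 0)
#' @param params an [inhibition_sim_params()] (used when concentration > 0)
#' @param gene,template_concentration labels carried on the output
#' @param seed optional integer seed
#' @return a `bulk_qpcr` object
#' @export
simulate_bulk_qpcr <- function(total_copies, replicates = 3,
                               config = sim_config(), concentration = 0,
                               params = inhibition_sim_params(),
                               gene = "target",
                               template_concentration = NA_real_,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(replicates >= 1, total_copies >= 0)
  m <- if (total_copies == 0) {
    integer(replicates)
  } else {
    as.integer(stats::rmultinom(1, total_copies,
                                rep(1 / replicates, replicates)))
  }
  p_dead <- complete_inhibition_prob(concentration, params)
  e_well <- config$efficiency_true + eprime_at(concentration, params, config)
  cq <- vapply(m, function(mi) {
    if (mi == 0) return(NA_real_)
    mi_alive <- if (p_dead > 0) stats::rbinom(1, mi, 1 - p_dead) else mi
    if (mi_alive == 0) return(NA_real_)
    amplification_cq(mi_alive, config, e_well = e_well) +
      stats::rnorm(1, 0, config$cq_noise_sd)
  }, numeric(1))
  cq[!is.na(cq) & cq > config$max_cycles] <- NA_real_
  cq[!is.na(cq) & cq <= 0] <- 1e-6
  bulk_qpcr_replicates(gene, template_concentration, cq,
                       max_cycles = config$max_cycles)
}

#' Simulate cell loading across the chip
#'
#' Places `n_cells` cells uniformly at random into the wells and tallies
#' the occupancy histogram.
#'
#' @param n_cells number of cells loaded
#' @param n_wells number of wells (default 2500)
#' @param seed optional integer seed
#' @return list with `observation` (an [occupancy_observation()]) and
#'   `cells_per_well` (integer vector)
#' @export
simulate_cell_loading <- function(n_cells, n_wells = 2500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- partition_molecules(n_cells, n_wells)
  tab <- table(counts)
  obs <- occupancy_observation(n_cells, as.list(tab), n_wells = n_wells)
  list(observation = obs, cells_per_well = counts)
}

#' EMT expression scenario
#'
#' Per-gene, per-condition lognormal expression for the default
#' epithelial-mesenchymal-transition time course (control plus 1, 2 and 4
#' days of TGF-beta-1): N-cadherin rises monotonically (2x per step),
#' vimentin rises then falls, E-cadherin stays flat (the null gene), and
#' GAPDH is the flat high-expression reference. `meanlog` values are
#' natural-log copies; `sdlog` is the cell-to-cell spread.
#'
#' @param genes named list: per gene, numeric vector of geometric-mean
#'   copies per condition (recycled across conditions if length 1)
#' @param conditions condition labels, in time order
#' @param sdlog lognormal sd (natural log scale) shared by all genes
#' @param n_cells_loaded cells loaded per gene x condition chip
#' @return an `emt_scenario` list
#' @export
emt_scenario <- function(genes = list(
                           GAPDH = 200,
                           `E-cadherin` = 50,
                           `N-cadherin` = c(5, 10, 20, 40),
                           vimentin = c(20, 80, 160, 40)),
                         conditions = c("control", "d1", "d2", "d4"),
                         sdlog = 0.8, n_cells_loaded = 500) {
  stopifnot(sdlog > 0, n_cells_loaded > 0)
  genes <- lapply(genes, function(g) {
    if (length(g) == 1) rep(g, length(conditions)) else g
  })
  stopifnot(all(vapply(genes, length, integer(1)) == length(conditions)))
  structure(list(genes = genes, conditions = conditions, sdlog = sdlog,
                 n_cells_loaded = n_cells_loaded), class = "emt_scenario")
}

#' Simulate a single-cell EMT expression experiment
#'
#' For each gene x condition, loads cells onto a chip
#' ([simulate_cell_loading()]); each occupied well's copy number is the sum
#' of its cells' lognormal draws (doublets sum), converted to a Cq through
#' the base-2 single-cell model `Cq = cq1 - log2(copies)` plus noise.
#'
#' @param scenario an [emt_scenario()]
#' @param config a [sim_config()] (supplies `cq1_true`, noise, well count)
#' @param seed optional integer seed
#' @return data.frame with columns `well_id`, `gene`, `condition`, `cq`,
#'   `copies_observed`, `n_cells_true`, `copies_true`
#' @export
simulate_emt_experiment <- function(scenario = emt_scenario(),
                                    config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in names(scenario$genes)) {
    for (ci in seq_along(scenario$conditions)) {
      cond <- scenario$conditions[ci]
      gm <- scenario$genes[[g]][ci]
      loading <- simulate_cell_loading(scenario$n_cells_loaded,
                                       config$n_partitions)
      counts <- loading$cells_per_well
      occ <- which(counts >= 1)
      n_cells_in <- counts[occ]
      copies_true <- vapply(seq_along(occ), function(i) {
        sum(stats::rlnorm(n_cells_in[i], meanlog = log(gm),
                          sdlog = scenario$sdlog))
      }, numeric(1))
      cq <- config$cq1_true - log2(copies_true) +
        stats::rnorm(length(occ), 0, config$cq_noise_sd)
      cq <- pmin(cq, config$max_cycles)
      rows[[length(rows) + 1]] <- data.frame(
        well_id = sprintf("W%04d", occ), gene = g, condition = cond,
        cq = cq, copies_observed = copies_per_cell(cq, config$cq1_true),
        n_cells_true = n_cells_in, copies_true = copies_true,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
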