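# Poisson model of cell loading across the microwell chip.
#
# Cells settle into wells independently and uniformly at random, so the
# per-well occupancy is Poisson with rate N/n for N input cells over n
# wells. The same zero-truncated counting used for molecules recovers the
# input number from the count of occupied (reactive) wells.

#' Estimate the number of input cells from the reactive-well count
#'
#' `X = log(1 - k'/n) / log(1 - 1/n)` — identical in form to
#' [total_copies_digital()], with cells in place of molecules.
#'
#' @param k_reactive number of wells containing at least one cell
#' @param n_wells number of wells (default 2500)
#' @return estimated total input cells
#' @export
estimate_input_cells <- function(k_reactive, n_wells = 2500) {
  total_copies_digital(k_reactive, n_wells)
}

#' Poisson occupancy probabilities
#'
#' For N input cells over n wells (rate `N/n`): proportions of wells with
#' zero cells `P0 = exp(-N/n)`, one cell `P1 = (N/n) exp(-N/n)`, and two or
#' more cells `P2+ = 1 - P0 - P1`. The three sum to one for any N.
#'
#' @param n_input total input cells N (>= 0, real-valued, vectorised)
#' @param n_wells number of wells (default 2500)
#' @return data.frame with columns `p0`, `p1`, `p2plus`
#' @export
occupancy_probabilities <- function(n_input, n_wells = 2500) {
  stopifnot(all(n_input >= 0))
  lambda <- n_input / n_wells
  p0 <- exp(-lambda)
  p1 <- lambda * exp(-lambda)
  data.frame(p0 = p0, p1 = p1, p2plus = 1 - p0 - p1)
}

#' Single-cell fraction of occupied wells
#'
#' The conditional probability, in percent, that an occupied well holds
#' exactly one cell: `100 P1 / (1 - P0)` with rate `N/n`. At 500 cells over
#' 2,500 wells this is 90.33%; it increases towards 100% as the load
#' decreases.
#'
#' @inheritParams occupancy_probabilities
#' @return percent of occupied wells holding a single cell
#' @export
single_cell_fraction <- function(n_input, n_wells = 2500) {
  stopifnot(all(n_input > 0))
  lambda <- n_input / n_wells
  100 * lambda * exp(-lambda) / (1 - exp(-lambda))
}

#' Build an occupancy observation
#'
#' @param n_input_nominal nominal number of cells loaded
#' @param counts_per_occupancy named integer vector or list: wells observed
#'   with `"0"`, `"1"`, `"2"` ... cells (categories above 1 are pooled into
#'   2+); or a full histogram `tabulate`-style vector starting at 0 cells
#' @param n_wells number of wells (default 2500); counts must sum to it
#' @return object of class `occupancy_observation` with fields
#'   `n_input_nominal`, `n0`, `n1`, `n2plus`, `n_wells`
#' @export
occupancy_observation <- function(n_input_nominal, counts_per_occupancy,
                                  n_wells = 2500) {
  x <- unlist(counts_per_occupancy)
  if (is.null(names(x))) names(x) <- as.character(seq_along(x) - 1)
  occ <- as.integer(names(x))
  n0 <- sum(x[occ == 0])
  n1 <- sum(x[occ == 1])
  n2 <- sum(x[occ >= 2])
  if (n0 + n1 + n2 != n_wells) {
    stop("occupancy counts must sum to n_wells", call. = FALSE)
  }
  structure(list(n_input_nominal = n_input_nominal, n0 = n0, n1 = n1,
                 n2plus = n2, n_wells = n_wells),
            class = "occupancy_observation")
}

#' Fit the Poisson occupancy model to observed cell distributions
#'
#' Compares observed per-category proportions (0 / 1 / 2+ cells per well)
#' across load levels against the closed-form Poisson curves
#' `P0(N), P1(N), P2+(N)` with the well count fixed at `n_wells`, and
#' reports the per-category coefficient of determination. With `n_wells`
#' fixed the curves have no free parameters, so the regression reduces to
#' goodness of fit of the theoretical model. Optionally the per-load N is
#' taken from the data (occupied-well inversion) instead of the nominal
#' loads.
#'
#' @param observations list of `occupancy_observation`s (>= 3 load levels)
#' @param predictor `"nominal"` (default; use the nominal loads as N) or
#'   `"estimated"` (invert the occupied-well count per load)
#' @return object of class `occupancy_model_fit`: list with `table`
#'   (per-load observed and predicted proportions), `r_squared`
#'   (named vector over p0/p1/p2plus), `estimated_N_per_load`
#' @export
fit_poisson_occupancy <- function(observations,
                                  predictor = c("nominal", "estimated")) {
  predictor <- match.arg(predictor)
  if (inherits(observations, "occupancy_observation")) {
    observations <- list(observations)
  }
  if (length(observations) < 3) stop("need >= 3 load levels", call. = FALSE)
  tab <- do.call(rbind, lapply(observations, function(o) {
    data.frame(n_nominal = o$n_input_nominal, n_wells = o$n_wells,
               obs_p0 = o$n0 / o$n_wells, obs_p1 = o$n1 / o$n_wells,
               obs_p2plus = o$n2plus / o$n_wells,
               n_estimated = estimate_input_cells(o$n1 + o$n2plus, o$n_wells))
  }))
  N <- if (predictor == "nominal") tab$n_nominal else tab$n_estimated
  pred <- occupancy_probabilities(N, tab$n_wells[1])
  tab$pred_p0 <- pred$p0
  tab$pred_p1 <- pred$p1
  tab$pred_p2plus <- pred$p2plus
  r2_of <- function(obs, fit) {
    ss_tot <- sum((obs - mean(obs))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((obs - fit)^2) / ss_tot
  }
  r2 <- c(p0 = r2_of(tab$obs_p0, tab$pred_p0),
          p1 = r2_of(tab$obs_p1, tab$pred_p1),
          p2plus = r2_of(tab$obs_p2plus, tab$pred_p2plus))
  structure(list(table = tab, r_squared = r2,
                 estimated_N_per_load = tab$n_estimated),
            class = "occupancy_model_fit")
}

#' Recommend a cell load for a target single-cell fraction
#'
#' Smallest input-cell number whose single-cell fraction still meets the
#' target — in practice the largest load satisfying it, found by bisection
#' on the strictly decreasing [single_cell_fraction()].
#'
#' @param target_single_fraction target percent of occupied wells holding
#'   one cell (0 < target < 100)
#' @param n_wells number of wells (default 2500)
#' @return recommended number of cells to load (real)
#' @export
recommend_loading <- function(target_single_fraction, n_wells = 2500) {
  if (target_single_fraction >= 100) {
    stop("a 100% single-cell fraction is unattainable at any positive load",
         call. = FALSE)
  }
  if (target_single_fraction <= 0) stop("target must be in (0, 100)", call. = FALSE)
  f <- function(N) single_cell_fraction(N, n_wells) - target_single_fraction
  upper <- n_wells
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-9, upper), tol = 1e-9)$root
}

#' @export
print.occupancy_model_fit <- function(x, ...) {
  cat("<occupancy_model_fit> per-category R^2:",
      sprintf("P0=%.4f P1=%.4f P2+=%.4f\n",
              x$r_squared[["p0"]], x$r_squared[["p1"]], x$r_squared[["p2plus"]]))
  invisible(x)
}
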