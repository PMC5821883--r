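# Serial-dilution fitting and single-copy Cq anchoring.
#
# A 10-fold dilution series measured on the chip shows two regimes: a linear
# Cq-vs-log10(concentration) range at high template, and a plateau at low
# template where nearly every positive well holds a single molecule and the
# mean positive-well Cq stops moving. The plateau mean defines the
# single-copy Cq (Cq1), the anchor that converts any Cq to copy numbers.

#' Build a dilution series
#'
#' @param levels a list, one element per dilution level, each a list with
#'   `concentration` (copies/uL, > 0), `cq_values` (numeric replicate or
#'   per-well Cq values), and optionally `run` (a `chip_run`). Alternatively
#'   a data.frame with columns `concentration` and `cq` (long format,
#'   one row per replicate measurement).
#' @return object of class `dilution_series`, levels sorted by increasing
#'   concentration
#' @export
dilution_series <- function(levels) {
  if (is.data.frame(levels)) {
    stopifnot(all(c("concentration", "cq") %in% names(levels)))
    levels <- lapply(split(levels, levels$concentration), function(g) {
      list(concentration = g$concentration[1], cq_values = g$cq)
    })
  }
  conc <- vapply(levels, function(l) l$concentration, numeric(1))
  if (any(conc <= 0)) stop("concentrations must be strictly positive", call. = FALSE)
  levels <- levels[order(conc)]
  structure(list(levels = levels), class = "dilution_series")
}

#' Per-level mean Cq of a dilution series
#' @param series a `dilution_series`
#' @return data.frame with `concentration`, `mean_cq`, `sd_cq`, `n`
#' @export
level_means <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  rows <- lapply(series$levels, function(l) {
    cq <- l$cq_values[!is.na(l$cq_values)]
    data.frame(concentration = l$concentration,
               mean_cq = if (length(cq)) mean(cq) else NA_real_,
               sd_cq = if (length(cq) > 1) stats::sd(cq) else 0,
               n = length(cq))
  })
  do.call(rbind, rows)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`, stored as a fraction (1.0 = perfect doubling
#' per cycle, reported as 100%). The canonical slope -3.3219 cycles per
#' 10-fold dilution gives E = 1.
#'
#' @param slope standard-curve slope (cycles per log10 concentration, < 0)
#' @return efficiency fraction
#' @export
efficiency_from_slope <- function(slope) {
  10^(-1 / slope) - 1
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of the per-level mean Cq on log10(concentration)
#' over the chosen levels; the slope yields the amplification efficiency
#' `E = 10^(-1/slope) - 1`.
#'
#' @param series a `dilution_series`
#' @param levels integer indices of the levels to fit (default: all); must
#'   cover at least two distinct concentrations
#' @return object of class `standard_curve_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency_fraction`, `efficiency_percent`,
#'   `linear_range` (the fitted level indices)
#' @export
fit_standard_curve <- function(series, levels = NULL) {
  lm_df <- level_means(series)
  if (is.null(levels)) levels <- seq_len(nrow(lm_df))
  df <- lm_df[levels, , drop = FALSE]
  df <- df[!is.na(df$mean_cq), , drop = FALSE]
  if (length(unique(df$concentration)) < 2) {
    stop("need at least two distinct concentrations to fit", call. = FALSE)
  }
  fit <- stats::lm(mean_cq ~ log10(concentration), data = df)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((df$mean_cq - mean(df$mean_cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency_fraction = efficiency_from_slope(slope),
                 efficiency_percent = 100 * efficiency_from_slope(slope),
                 linear_range = levels),
            class = "standard_curve_fit")
}

#' Split a dilution series into linear and digital (plateau) regimes
#'
#' Scanning from the lowest concentration upward, the plateau is the maximal
#' run of levels whose consecutive mean-Cq differences stay below
#' `anchor_tolerance` despite the (>= 2-fold) concentration change; the
#' remaining higher levels form the linear range. In the plateau nearly
#' every positive well holds one molecule, so the mean Cq is pinned at the
#' single-copy Cq.
#'
#' @param series a `dilution_series` with >= 3 levels
#' @param anchor_tolerance maximum consecutive mean-Cq difference (cycles)
#'   within the plateau (default 0.5)
#' @return list with integer index vectors `plateau_levels` and
#'   `linear_levels` (indices into the concentration-sorted series; plateau
#'   may be empty)
#' @export
detect_digital_regime <- function(series, anchor_tolerance = 0.5) {
  lm_df <- level_means(series)
  n <- nrow(lm_df)
  if (n < 3) stop("need at least 3 levels", call. = FALSE)
  plateau_end <- 1L
  for (i in seq_len(n - 1)) {
    ratio <- lm_df$concentration[i + 1] / lm_df$concentration[i]
    if (ratio >= 2 && !is.na(lm_df$mean_cq[i + 1]) && !is.na(lm_df$mean_cq[i]) &&
        abs(lm_df$mean_cq[i + 1] - lm_df$mean_cq[i]) < anchor_tolerance) {
      plateau_end <- i + 1L
    } else {
      break
    }
  }
  if (plateau_end == 1L) {
    # a single lowest level is not evidence of a plateau
    list(plateau_levels = integer(0), linear_levels = seq_len(n))
  } else {
    list(plateau_levels = seq_len(plateau_end),
         linear_levels = if (plateau_end < n) (plateau_end + 1L):n else integer(0))
  }
}

#' Estimate the single-copy Cq anchor
#'
#' Pools positive-well Cq values from chip runs in the digital regime, where
#' the probability that a positive well holds a single molecule exceeds
#' `min_single_copy_prob`. With `weighting = "per_well"` every positive well
#' contributes equally; with `"per_level"` each run's mean contributes
#' equally (the two differ when positive counts differ across levels).
#'
#' @param runs list of `chip_run`s from digital-regime dilution levels
#' @param weighting `"per_well"` (default) or `"per_level"`
#' @param min_single_copy_prob minimum `P(X <= 1)` (fraction, default 0.95)
#'   a run must satisfy, computed from its own positive count
#' @return object of class `single_copy_anchor`: list with `cq1_mean`,
#'   `cq1_sd`, `n_wells`, `source_levels`
#' @export
estimate_single_copy_cq <- function(runs, weighting = c("per_well", "per_level"),
                                    min_single_copy_prob = 0.95) {
  weighting <- match.arg(weighting)
  if (inherits(runs, "chip_run")) runs <- list(runs)
  qualifying <- list()
  for (r in runs) {
    counts <- status_counts(r)
    k <- counts[["positive"]]
    p1 <- single_copy_probability(k, r$n_partitions, counts[["fail"]],
                                  "at_most_one") / 100
    if (k > 0 && p1 >= min_single_copy_prob) qualifying <- c(qualifying, list(r))
  }
  if (length(qualifying) == 0) {
    stop("no runs qualify for the digital regime (single-copy probability ",
         "below threshold or no positives)", call. = FALSE)
  }
  per_run_cq <- lapply(qualifying, function(r) {
    r$wells$cq[r$wells$status == "positive"]
  })
  if (weighting == "per_well") {
    pooled <- unlist(per_run_cq)
    cq1 <- mean(pooled)
    s <- if (length(pooled) > 1) stats::sd(pooled) else 0
  } else {
    means <- vapply(per_run_cq, mean, numeric(1))
    cq1 <- mean(means)
    s <- if (length(means) > 1) stats::sd(means) else 0
  }
  structure(list(cq1_mean = cq1, cq1_sd = s,
                 n_wells = length(unlist(per_run_cq)),
                 source_levels = vapply(qualifying, function(r) {
                   c0 <- r$metadata$nominal_concentration
                   if (is.null(c0)) NA_real_ else c0
                 }, numeric(1))),
            class = "single_copy_anchor")
}

#' Convert a Cq value to copy numbers via the single-copy anchor
#'
#' `N = (1 + E)^(Cq1 - Cq)`: one copy at the anchor, doubling (at E = 1) for
#' every cycle below it. Strictly decreasing in Cq.
#'
#' @param cq Cq value(s)
#' @param anchor a `single_copy_anchor`, or a numeric Cq1 value
#' @param efficiency_fraction amplification efficiency E (> 0)
#' @return estimated copy number(s)
#' @export
copies_from_cq <- function(cq, anchor, efficiency_fraction) {
  stopifnot(efficiency_fraction > 0)
  cq1 <- if (inherits(anchor, "single_copy_anchor")) anchor$cq1_mean else anchor
  (1 + efficiency_fraction)^(cq1 - cq)
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("<standard_curve_fit> slope=%.4f intercept=%.2f R2=%.4f E=%.2f%%\n",
              x$slope, x$intercept, x$r_squared, x$efficiency_percent))
  invisible(x)
}

#' @export
print.single_copy_anchor <- function(x, ...) {
  cat(sprintf("<single_copy_anchor> Cq1 = %.2f +/- %.2f (%d wells)\n",
              x$cq1_mean, x$cq1_sd, x$n_wells))
  invisible(x)
}
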