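# Poisson digital quantification from positive-partition counts.
#
# The chip partitions a sample into n wells; molecules land in wells
# independently, so per-well copy numbers are Poisson. Counting positive
# wells k (at least one molecule amplified) gives
#   lambda = -ln(1 - k/n')   and   SumN = log(1 - k/n') / log(1 - 1/n'),
# where n' is the effective partition count after removing failed wells and
# the expected primer-dimer false positives.

#' Effective partition count
#'
#' Number of informative partitions after removing failed wells (unfilled or
#' bubbled) and the expected number of primer-dimer false positives derived
#' from no-template controls: `n' = n - n_fail - n_dimer`.
#'
#' @param n total partitions (2500 for the standard chip)
#' @param n_fail failed-well count
#' @param n_dimer expected primer-dimer false positives per chip (real-valued
#'   mean across NTC replicates; default 0)
#' @return effective partition count `n'` (real)
#' @export
effective_partitions <- function(n, n_fail = 0, n_dimer = 0) {
  stopifnot(n > 0, n_fail >= 0, n_dimer >= 0)
  n_eff <- n - n_fail - n_dimer
  if (n_eff <= 0) {
    stop("effective partition count is non-positive: check n_fail/n_dimer",
         call. = FALSE)
  }
  n_eff
}

#' Mean copies per partition from the positive count
#'
#' `lambda = -ln(1 - k/n_eff)`: the Poisson rate whose zero-class matches the
#' observed fraction of negative partitions.
#'
#' @param k positive-partition count (real-valued replicate means accepted)
#' @param n_eff effective partition count
#' @return lambda (copies per partition)
#' @export
lambda_from_positives <- function(k, n_eff) {
  stopifnot(k >= 0)
  if (k >= n_eff) {
    stop("all effective partitions positive: sample saturated, ",
         "concentration not quantifiable", call. = FALSE)
  }
  -log(1 - k / n_eff)
}

#' Total initial copies from the positive count
#'
#' `SumN = log(1 - k/n_eff) / log(1 - 1/n_eff)`. Equivalent to
#' `lambda * n_eff` up to the discreteness correction (< 0.03% at n = 2500);
#' approaches `k` as occupancy goes to zero.
#'
#' @inheritParams lambda_from_positives
#' @return estimated total copies loaded on the chip
#' @export
total_copies_digital <- function(k, n_eff) {
  stopifnot(k >= 0)
  if (k >= n_eff) {
    stop("all effective partitions positive: sample saturated, ",
         "concentration not quantifiable", call. = FALSE)
  }
  log(1 - k / n_eff) / log(1 - 1 / n_eff)
}

#' Poisson per-partition copy-number probability
#'
#' `P(X = x) = exp(-lambda) lambda^x / x!`, the probability that a partition
#' holds exactly `x` copies.
#'
#' @param lambda_mean mean copies per partition
#' @param x copy number (non-negative integer, vectorised)
#' @return probability
#' @export
poisson_copy_pmf <- function(lambda_mean, x) {
  stopifnot(all(lambda_mean >= 0))
  stats::dpois(x, lambda_mean)
}

#' Probability that a partition holds (at most) one copy
#'
#' With `lambda = k / (n - n_fail)`, returns as a percentage either
#' `P(X <= 1) = exp(-lambda) (1 + lambda)` (`"at_most_one"`, the convention
#' that reproduces the chip's low-concentration characterisation) or the
#' conditional `P(X = 1 | X >= 1) = lambda exp(-lambda) / (1 - exp(-lambda))`
#' (`"exactly_one_given_positive"`).
#'
#' @param k positive count (real-valued means accepted)
#' @param n total partitions
#' @param n_fail failed wells
#' @param convention `"at_most_one"` (default) or
#'   `"exactly_one_given_positive"`
#' @return probability in percent
#' @export
single_copy_probability <- function(k, n = 2500, n_fail = 0,
                                    convention = c("at_most_one",
                                                   "exactly_one_given_positive")) {
  convention <- match.arg(convention)
  stopifnot(k >= 0, k < n - n_fail)
  lambda <- k / (n - n_fail)
  if (convention == "at_most_one") {
    100 * exp(-lambda) * (1 + lambda)
  } else {
    if (k == 0) {
      stop("P(X = 1 | positive) is undefined when no wells are positive",
           call. = FALSE)
    }
    100 * lambda * exp(-lambda) / (1 - exp(-lambda))
  }
}

#' Quantify one chip run digitally
#'
#' Composes the Poisson estimators: counts positives and fails, derives the
#' expected primer-dimer count from an NTC reference if supplied, forms the
#' effective partition count, and returns lambda, the estimated total copies,
#' one-copy probabilities, and a normal-approximation confidence interval on
#' the total (var(lambda) ~ (exp(lambda) - 1) / n_eff, standard partition
#' statistics).
#'
#' @param run a called `chip_run` (see [call_wells()])
#' @param ntc an NTC `chip_run` (or list of them), or `NULL`
#' @param subtract_dimers subtract the NTC-derived expected false-positive
#'   count from k before estimation (default `TRUE` when an NTC is given)
#' @param max_cq positive-call threshold used for the NTC positives
#' @param conf_level confidence level for the copy-number interval
#' @return object of class `digital_quant`: list with `k_positive`,
#'   `n_partitions`, `n_fail`, `n_dimer`, `n_effective`, `lambda_mean`,
#'   `total_copies`, `ci_lower`, `ci_upper`, `p_exactly_one`, `p_at_most_one`
#' @export
quantify_run <- function(run, ntc = NULL, subtract_dimers = !is.null(ntc),
                         max_cq = 40, conf_level = 0.95) {
  stopifnot(inherits(run, "chip_run"))
  if (!is.null(ntc)) run <- call_wells(run, max_cq = max_cq, ntc_reference = ntc)
  counts <- status_counts(run)
  k_obs <- counts[["positive"]] + counts[["dimer"]]
  n_fail <- counts[["fail"]]
  n_dimer <- if (is.null(run$n_dimer_expected)) 0 else run$n_dimer_expected
  quantify_counts(k_obs, n = run$n_partitions, n_fail = n_fail,
                  n_dimer = n_dimer, subtract_dimers = subtract_dimers,
                  conf_level = conf_level)
}

#' Quantify replicate chip runs
#'
#' Replicate chips of the same sample are summarised by averaging the
#' positive and failed counts across replicates (and the NTC positives
#' across NTC replicates) before applying the nonlinear Poisson transform,
#' which is how replicate means such as k = 454.50 arise in practice.
#'
#' @param runs list of called `chip_run`s (replicates of one sample)
#' @param ntc_runs optional list of NTC `chip_run`s
#' @param subtract_dimers subtract the NTC mean false-positive count from the
#'   mean k (default `TRUE` when NTCs are given)
#' @inheritParams quantify_run
#' @return a `digital_quant` object (see [quantify_run()])
#' @export
quantify_replicates <- function(runs, ntc_runs = NULL,
                                subtract_dimers = !is.null(ntc_runs),
                                max_cq = 40, conf_level = 0.95) {
  stopifnot(length(runs) >= 1)
  cs <- vapply(runs, function(r) status_counts(r), integer(4))
  k_mean <- mean(cs["positive", ] + cs["dimer", ])
  fail_mean <- mean(cs["fail", ])
  n <- runs[[1]]$n_partitions
  n_dimer <- 0
  if (!is.null(ntc_runs)) {
    kn <- vapply(ntc_runs, function(r) {
      sum(!is.na(r$wells$cq) & r$wells$cq <= max_cq & r$wells$status != "fail")
    }, numeric(1))
    n_dimer <- mean(kn)
  }
  quantify_counts(k_mean, n = n, n_fail = fail_mean, n_dimer = n_dimer,
                  subtract_dimers = subtract_dimers, conf_level = conf_level)
}

# shared core over (possibly real-valued) counts
quantify_counts <- function(k_obs, n, n_fail, n_dimer, subtract_dimers,
                            conf_level = 0.95) {
  k <- if (subtract_dimers) max(0, k_obs - n_dimer) else k_obs
  n_eff <- effective_partitions(n, n_fail,
                                if (subtract_dimers) n_dimer else 0)
  if (k == 0) {
    res <- list(lambda_mean = 0, total_copies = 0, ci_lower = 0, ci_upper = 0,
                p_at_most_one = 100, p_exactly_one = NA_real_)
  } else {
    lambda <- lambda_from_positives(k, n_eff)
    total <- total_copies_digital(k, n_eff)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se_lambda <- sqrt((exp(lambda) - 1) / n_eff)
    lo <- max(0, lambda - z * se_lambda)
    hi <- lambda + z * se_lambda
    denom <- -log(1 - 1 / n_eff)
    res <- list(
      lambda_mean = lambda, total_copies = total,
      ci_lower = lo / denom, ci_upper = hi / denom,
      p_at_most_one = single_copy_probability(k, n, n_fail, "at_most_one"),
      p_exactly_one = single_copy_probability(k, n, n_fail,
                                              "exactly_one_given_positive"))
  }
  structure(c(list(k_positive = k, n_partitions = n, n_fail = n_fail,
                   n_dimer = n_dimer, n_effective = n_eff), res),
            class = "digital_quant")
}

#' @export
print.digital_quant <- function(x, ...) {
  cat(sprintf(paste0("<digital_quant> k=%.2f of n'=%.2f  lambda=%.4f  ",
                     "total copies=%.2f [%.2f, %.2f]\n"),
              x$k_positive, x$n_effective, x$lambda_mean, x$total_copies,
              x$ci_lower, x$ci_upper))
  cat(sprintf("  P(X<=1)=%.1f%%  P(X=1|positive)=%.1f%%\n",
              x$p_at_most_one, x$p_exactly_one))
  invisible(x)
}
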