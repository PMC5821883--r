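# Inhibitor (heparin) quantification.
#
# An inhibited reaction is modelled as still reaching the detection
# threshold K, but with a reduced effective efficiency E + E' (E' <= 0):
#   K = N (1 + E + E')^Cq'          (inhibited, true copies N)
#   K = N' (1 + E)^Cq'              (apparent copies N' at nominal E)
# Equating the two at the shared threshold yields the inhibitory parameter,
# and a no-inhibitor control (NIC) gives percent-of-control directly from
# the Cq shift. Digital chips instead compare Poisson copy estimates, which
# only lose completely inhibited wells, not efficiency.

#' Percent-of-control from a Cq shift
#'
#' `100 (1 + E)^(Cq_NIC - Cq')`: the apparent template fraction remaining
#' relative to the no-inhibitor control. Equals 100 when the inhibited Cq
#' matches the control and halves per lost doubling at E = 1.
#'
#' @param cq_inhibited Cq of the inhibited reaction (Cq')
#' @param cq_nic Cq of the no-inhibitor control
#' @param efficiency_fraction amplification efficiency E (> 0)
#' @return percent of control
#' @export
percent_of_control <- function(cq_inhibited, cq_nic, efficiency_fraction) {
  stopifnot(efficiency_fraction > 0)
  100 * (1 + efficiency_fraction)^(cq_nic - cq_inhibited)
}

#' Digital percent-of-control from positive counts
#'
#' Ratio of Poisson copy estimates, `100 SumN(k_inhibited) / SumN(k_nic)`,
#' using [total_copies_digital()]. Partition counting only registers wells
#' whose reactions were completely suppressed, which is what makes the
#' digital readout inhibitor-tolerant.
#'
#' @param k_inhibited positive count of the inhibited chip
#' @param k_nic positive count of the no-inhibitor control chip
#' @param n_eff effective partition count (shared)
#' @return percent of control
#' @export
digital_percent_of_control <- function(k_inhibited, k_nic, n_eff = 2500) {
  if (k_nic <= 0) stop("control chip has no positive wells", call. = FALSE)
  if (k_inhibited == 0) return(0)
  100 * total_copies_digital(k_inhibited, n_eff) /
    total_copies_digital(k_nic, n_eff)
}

#' Inhibitory efficiency parameter E'
#'
#' From the threshold identity `N (1 + E + E')^Cq' = N' (1 + E)^Cq'`:
#' `E' = (1 + E) ((N'/N)^(1/Cq') - 1)`. Zero when apparent equals true
#' copies; negative under inhibition.
#'
#' @param n_true true initial copies N
#' @param n_apparent apparent copies N' recovered at nominal efficiency
#' @param efficiency_fraction nominal efficiency E
#' @param cq_inhibited observed Cq of the inhibited reaction
#' @return E' (efficiency decrement, <= 0 under inhibition)
#' @export
inhibitory_parameter <- function(n_true, n_apparent, efficiency_fraction,
                                 cq_inhibited) {
  stopifnot(n_true > 0, n_apparent > 0, cq_inhibited > 0)
  (1 + efficiency_fraction) * ((n_apparent / n_true)^(1 / cq_inhibited) - 1)
}

#' Final in-reaction inhibitor concentration from a stock concentration
#'
#' Heparin stocks are added as 1 part in `dilution_factor` parts of reaction
#' mix (default 1 uL in 20 uL), so stocks of 0.02-5.0 IU/mL correspond to
#' final concentrations of 0.001-0.25 IU/mL.
#'
#' @param stock stock concentration(s), IU/mL
#' @param dilution_factor reaction dilution (default 20)
#' @return final concentration(s), IU/mL
#' @export
final_inhibitor_concentration <- function(stock, dilution_factor = 20) {
  stock / dilution_factor
}

#' Fit an IC50 inhibition curve
#'
#' Nonlinear least squares of a log-logistic (Hill) dose-response
#' `y(c) = bottom + (top - bottom) / (1 + (c / ic50)^h)` to
#' percent-of-control points. By default the asymptotes are fixed at
#' top = 100 and bottom = 0, since percent-of-control is defined on
#' [0, 100]; `free_asymptotes = TRUE` frees them. Zero-concentration (NIC)
#' points are excluded from the abscissa.
#'
#' @param points data.frame with columns `concentration` (IU/mL) and
#'   `percent_of_control`; replicate rows per concentration are allowed
#' @param free_asymptotes fit top/bottom as free parameters (default FALSE)
#' @return object of class `inhibition_curve_fit`: list with `ic50`,
#'   `hill_slope`, `top`, `bottom`, `r_squared`, `points`, `fit` (the nls
#'   object)
#' @export
fit_ic50 <- function(points, free_asymptotes = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "percent_of_control") %in% names(points)))
  df <- points[points$concentration > 0, , drop = FALSE]
  if (length(unique(df$concentration)) < 4) {
    stop("need at least 4 positive inhibitor concentrations", call. = FALSE)
  }
  y <- df$percent_of_control
  if (max(y) - min(y) < 10) {
    stop("no inhibition transition in the data; IC50 not identifiable",
         call. = FALSE)
  }
  df$lc <- log(df$concentration)
  # start log(ic50) near the concentration bracketing 50% of control
  o <- order(df$lc)
  start_lic50 <- stats::approx(y[o], df$lc[o], xout = 50, ties = mean,
                               rule = 2)$y
  ctrl <- stats::nls.control(maxiter = 200, warnOnly = TRUE)
  if (free_asymptotes) {
    fit <- minpack.lm::nlsLM(
      percent_of_control ~ bottom + (top - bottom) / (1 + exp(h * (lc - lic50))),
      data = df,
      start = list(lic50 = start_lic50, h = 1, top = max(y), bottom = min(y)),
      control = ctrl)
  } else {
    fit <- minpack.lm::nlsLM(
      percent_of_control ~ 100 / (1 + exp(h * (lc - lic50))),
      data = df, start = list(lic50 = start_lic50, h = 1), control = ctrl)
  }
  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(ic50 = exp(unname(cf[["lic50"]])),
                 hill_slope = unname(cf[["h"]]),
                 top = if (free_asymptotes) unname(cf[["top"]]) else 100,
                 bottom = if (free_asymptotes) unname(cf[["bottom"]]) else 0,
                 r_squared = r2, points = points, fit = fit),
            class = "inhibition_curve_fit")
}

#' Predict percent-of-control from a fitted inhibition curve
#' @param object an `inhibition_curve_fit`
#' @param concentration concentrations (IU/mL, > 0)
#' @param ... unused
#' @return predicted percent-of-control
#' @export
predict.inhibition_curve_fit <- function(object, concentration, ...) {
  lc <- log(concentration)
  lic50 <- log(object$ic50)
  object$bottom + (object$top - object$bottom) /
    (1 + exp(object$hill_slope * (lc - lic50)))
}

#' @export
print.inhibition_curve_fit <- function(x, ...) {
  cat(sprintf("<inhibition_curve_fit> IC50 = %.4g IU/mL, hill = %.2f, R2 = %.4f\n",
              x$ic50, x$hill_slope, x$r_squared))
  invisible(x)
}
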