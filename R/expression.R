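# Single-cell gene-expression profiling.
#
# Each reactive well is assumed to hold a single cell; its Cq converts to
# an initial mRNA copy number via the single-copy anchor, A = 2^(Cq1 - Cq).
# Copy numbers are summarised by geometric means (the arithmetic mean on
# the Cq scale) and compared across conditions with Kolmogorov-Smirnov
# tests: one-sample against normal/lognormal families, two-sample between
# treatment time points.

#' Initial copies per cell from a well Cq
#'
#' `A = 2^(cq1_ref - cq)`: one copy at the reference single-copy Cq,
#' doubling for every cycle below it.
#'
#' @param cq well Cq value(s)
#' @param cq1_ref single-copy reference Cq (anchored on a reference gene,
#'   e.g. GAPDH)
#' @return copy number(s)
#' @export
copies_per_cell <- function(cq, cq1_ref) {
  2^(cq1_ref - cq)
}

#' Geometric mean copy number
#'
#' `exp(mean(log(copies)))` over reactive wells. Identical to converting
#' the arithmetic-mean Cq: geometric-mean copies = `2^(cq1_ref - mean(Cq))`.
#'
#' @param copies positive copy numbers (non-finite / non-positive entries
#'   are rejected)
#' @return geometric mean
#' @export
geometric_mean_copies <- function(copies) {
  copies <- copies[!is.na(copies)]
  if (length(copies) == 0) stop("no reactive wells to average", call. = FALSE)
  if (any(copies <= 0)) stop("copy numbers must be positive", call. = FALSE)
  exp(mean(log(copies)))
}

#' One-sample Kolmogorov-Smirnov test against a normal or lognormal family
#'
#' Tests whether values are consistent with a normal (or lognormal, i.e.
#' normal after log transform) distribution. If `params` is omitted, the
#' mean and SD are estimated from the data; the asymptotic p-value is then
#' biased (Lilliefors effect) and an optional parametric-bootstrap p-value
#' that re-estimates moments under the null is provided
#' (`bootstrap = TRUE`).
#'
#' @param values sample values (copy numbers); must be positive when
#'   `family = "lognormal"`
#' @param family `"normal"` or `"lognormal"`
#' @param params optional `c(mean, sd)` of the reference distribution (on
#'   the log scale for lognormal); when given the test is exact-null
#' @param bootstrap compute a parametric-bootstrap p-value accounting for
#'   estimated moments
#' @param n_boot bootstrap replicates (default 200)
#' @return object of class `ks_result`: list with `statistic_D`, `p_value`,
#'   `p_value_bootstrap` (or `NA`), `test`, `n`
#' @export
ks_one_sample <- function(values, family = c("normal", "lognormal"),
                          params = NULL, bootstrap = FALSE, n_boot = 200) {
  family <- match.arg(family)
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  x <- if (family == "lognormal") {
    if (any(values <= 0)) {
      stop("lognormal test requires strictly positive values", call. = FALSE)
    }
    log(values)
  } else {
    values
  }
  if (stats::sd(x) == 0) {
    stop("degenerate (constant) sample: distribution test undefined",
         call. = FALSE)
  }
  estimated <- is.null(params)
  if (estimated) params <- c(mean(x), stats::sd(x))
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", params[1], params[2]))
  p_boot <- NA_real_
  if (bootstrap && estimated) {
    d_obs <- unname(kt$statistic)
    n <- length(x)
    d_null <- vapply(seq_len(n_boot), function(i) {
      xb <- stats::rnorm(n, params[1], params[2])
      unname(suppressWarnings(
        stats::ks.test(xb, "pnorm", mean(xb), stats::sd(xb))$statistic))
    }, numeric(1))
    p_boot <- (1 + sum(d_null >= d_obs)) / (n_boot + 1)
  }
  structure(list(statistic_D = unname(kt$statistic),
                 p_value = kt$p.value, p_value_bootstrap = p_boot,
                 test = paste0("one_sample_", family),
                 moments_estimated = estimated, n = length(x)),
            class = "ks_result")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS statistic with asymptotic p-value, computed on
#' log copies. The statistic is invariant under any common strictly
#' monotone transform, so log vs linear copies give identical results; the
#' log transform is applied for numerical hygiene only.
#'
#' @param a,b samples of copy numbers (positive)
#' @return a `ks_result` (see [ks_one_sample()])
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 5 || length(b) < 5) {
    stop("need at least 5 values per sample", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(log(a), log(b)))
  structure(list(statistic_D = unname(kt$statistic), p_value = kt$p.value,
                 p_value_bootstrap = NA_real_, test = "two_sample",
                 n = c(length(a), length(b))),
            class = "ks_result")
}

#' Log-binned histogram of copy numbers
#'
#' Equal-width bins in log10 copies; bin count by the Freedman-Diaconis
#' rule unless given.
#'
#' @param copies positive copy numbers
#' @param n_bins number of bins, or `NULL` for Freedman-Diaconis
#' @return list with `breaks` (log10 scale), `counts`, `mids`
#' @export
log_histogram <- function(copies, n_bins = NULL) {
  x <- log10(copies[!is.na(copies) & copies > 0])
  if (length(x) == 0) stop("no positive copy numbers", call. = FALSE)
  if (is.null(n_bins)) {
    h <- stats::IQR(x)
    if (h == 0) {
      n_bins <- 1L
    } else {
      bw <- 2 * h / length(x)^(1 / 3)
      n_bins <- max(1L, ceiling(diff(range(x)) / bw))
    }
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  if (n_bins == 1L) breaks <- c(min(x) - 0.5, max(x) + 0.5)
  hh <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = hh$breaks, counts = hh$counts, mids = hh$mids)
}

#' Profile gene expression across a treatment time course
#'
#' For each gene: converts well Cq values to per-cell copies against the
#' single-copy reference, computes per-condition geometric means and
#' log-binned histograms, and runs all pairwise two-sample KS tests between
#' conditions with Holm correction across the comparisons (raw p-values are
#' retained alongside).
#'
#' @param records data.frame with columns `well_id`, `gene`, `condition`,
#'   `cq` (and optionally `copies`; computed from `cq` when absent)
#' @param cq1_ref single-copy reference Cq used for the conversion (ignored
#'   when a `copies` column is present)
#' @param alpha significance level applied to Holm-adjusted p-values
#' @param min_n minimum wells per condition for testing (default 5)
#' @return object of class `expression_profile`: per-gene list with
#'   `geometric_means` (named by condition), `histograms`, `comparisons`
#'   (data.frame: condition pair, D, raw and Holm-adjusted p, significance)
#' @export
profile_timecourse <- function(records, cq1_ref = NULL, alpha = 0.05,
                               min_n = 5) {
  stopifnot(is.data.frame(records),
            all(c("gene", "condition") %in% names(records)))
  if (is.null(records$copies)) {
    if (is.null(cq1_ref)) {
      stop("cq1_ref required when records carry Cq values only", call. = FALSE)
    }
    records$copies <- copies_per_cell(records$cq, cq1_ref)
  }
  records <- records[!is.na(records$copies) & records$copies > 0, ]
  genes <- unique(records$gene)
  out <- lapply(genes, function(g) {
    rg <- records[records$gene == g, ]
    conds <- unique(rg$condition)
    by_cond <- split(rg$copies, factor(rg$condition, levels = conds))
    gm <- vapply(by_cond, geometric_mean_copies, numeric(1))
    hists <- lapply(by_cond, log_histogram)
    comparisons <- NULL
    if (length(conds) >= 2) {
      pairs <- utils::combn(conds, 2, simplify = FALSE)
      rows <- lapply(pairs, function(p) {
        a <- by_cond[[p[1]]]
        b <- by_cond[[p[2]]]
        if (length(a) < min_n || length(b) < min_n) {
          return(data.frame(condition_a = p[1], condition_b = p[2],
                            statistic_D = NA_real_, p_raw = NA_real_))
        }
        ks <- ks_two_sample(a, b)
        data.frame(condition_a = p[1], condition_b = p[2],
                   statistic_D = ks$statistic_D, p_raw = ks$p_value)
      })
      comparisons <- do.call(rbind, rows)
      comparisons$p_holm <- stats::p.adjust(comparisons$p_raw, method = "holm")
      comparisons$significant <- !is.na(comparisons$p_holm) &
        comparisons$p_holm < alpha
    }
    list(gene = g, n_per_condition = vapply(by_cond, length, integer(1)),
         geometric_means = gm, histograms = hists, comparisons = comparisons)
  })
  names(out) <- genes
  structure(list(genes = out, alpha = alpha), class = "expression_profile")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> %s: D = %.4f, p = %.4g\n",
              x$test, x$statistic_D, x$p_value))
  invisible(x)
}

#' @export
print.expression_profile <- function(x, ...) {
  for (g in x$genes) {
    cat(sprintf("gene %s: geometric means [%s]\n", g$gene,
                paste(sprintf("%s=%.2f", names(g$geometric_means),
                              g$geometric_means), collapse = ", ")))
    if (!is.null(g$comparisons)) {
      sig <- sum(g$comparisons$significant, na.rm = TRUE)
      cat(sprintf("  %d/%d pairwise KS comparisons significant (Holm, alpha=%g)\n",
                  sig, nrow(g$comparisons), x$alpha))
    }
  }
  invisible(x)
}
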