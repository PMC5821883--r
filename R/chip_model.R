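#' @keywords internal
"_PACKAGE"

WELL_STATUSES <- c("positive", "negative", "fail", "dimer")

#' Construct a chip run
#'
#' A chip run is the universal input object of the pipeline: the per-well
#' state of one digital qPCR run on a microwell chip (default 2,500
#' partitions of 20 nL arranged on a 50 x 50 grid). Each well carries an
#' identifier, grid coordinates, an optional quantification cycle (Cq),
#' optional endpoint fluorescence, and a call status.
#'
#' @param wells data.frame with columns `well_id` (character), `row`, `col`
#'   (0-based integer grid indices), `cq` (numeric cycles, `NA` for no
#'   amplification), optional `endpoint_fluorescence`, and `status`
#'   (one of `"positive"`, `"negative"`, `"fail"`, `"dimer"`). Missing
#'   `well_id` values are filled as `"R{row}C{col}"`; a missing `status`
#'   column is derived (Cq present -> positive, absent -> negative).
#' @param n_partitions total number of partitions on the chip (default 2500).
#' @param metadata named list; recognised entries are `gene`, `sample_label`,
#'   `nominal_concentration` (copies/uL), `inhibitor_concentration` (IU/mL)
#'   and `is_ntc` (logical).
#' @return An object of class `chip_run`: a list with elements `wells`,
#'   `n_partitions`, `metadata`, and `n_dimer_expected` (filled by
#'   [call_wells()] when an NTC reference is supplied).
#' @seealso [read_well_table()], [call_wells()], [summarize_run()]
#' @export
chip_run <- function(wells, n_partitions = 2500, metadata = list()) {
  stopifnot(is.data.frame(wells))
  required <- c("row", "col", "cq")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    stop("well table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(wells) != n_partitions) {
    stop(sprintf("well table has %d rows but the chip has %d partitions",
                 nrow(wells), n_partitions), call. = FALSE)
  }
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  wells$cq <- as.numeric(wells$cq)
  if (is.null(wells$well_id) || anyNA(wells$well_id)) {
    ids <- sprintf("R%dC%d", wells$row, wells$col)
    if (is.null(wells$well_id)) wells$well_id <- ids
    else wells$well_id[is.na(wells$well_id)] <- ids[is.na(wells$well_id)]
  }
  wells$well_id <- as.character(wells$well_id)
  if (is.null(wells$status)) {
    wells$status <- ifelse(is.na(wells$cq), "negative", "positive")
  }
  wells$status <- as.character(wells$status)
  wells$status[is.na(wells$status) | wells$status == ""] <-
    ifelse(is.na(wells$cq[is.na(wells$status) | wells$status == ""]),
           "negative", "positive")
  bad <- setdiff(unique(wells$status), WELL_STATUSES)
  if (length(bad) > 0) {
    stop("unknown well status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # status invariants: positives carry a Cq, negatives do not
  if (any(wells$status == "positive" & is.na(wells$cq))) {
    stop("positive wells must have a Cq value", call. = FALSE)
  }
  wells$cq[wells$status == "negative"] <- NA_real_
  grid_dim <- ceiling(sqrt(n_partitions))
  if (any(wells$row < 0 | wells$row >= grid_dim | wells$col < 0 | wells$col >= grid_dim)) {
    stop("row/col indices outside the chip grid", call. = FALSE)
  }
  structure(
    list(wells = wells, n_partitions = as.integer(n_partitions),
         metadata = metadata, n_dimer_expected = metadata$n_dimer_expected),
    class = "chip_run"
  )
}

#' Count wells by status
#' @param run a `chip_run`
#' @return named integer vector over positive/negative/fail/dimer
#' @export
status_counts <- function(run) {
  stopifnot(inherits(run, "chip_run"))
  out <- table(factor(run$wells$status, levels = WELL_STATUSES))
  stats::setNames(as.integer(out), WELL_STATUSES)
}

#' Read a per-well chip table from CSV
#'
#' Expects columns `well_id,row,col,cq,status` (`status` optional; `cq` empty
#' for no amplification). Wells lacking a Cq and not marked `fail` become
#' `negative`.
#'
#' @param path CSV file path.
#' @param n_partitions expected number of wells (default 2500); a mismatch is
#'   a dimension error.
#' @param metadata named list attached to the run (see [chip_run()]).
#' @return a `chip_run`
#' @export
read_well_table <- function(path, n_partitions = 2500, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well_id", "row", "col", "cq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("well-table CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  chip_run(df, n_partitions = n_partitions, metadata = metadata)
}

#' Write a chip run to a per-well CSV
#'
#' Inverse of [read_well_table()]; `write_well_table` then `read_well_table`
#' round-trips the well table exactly.
#'
#' @param run a `chip_run`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_well_table <- function(run, path) {
  stopifnot(inherits(run, "chip_run"))
  cols <- intersect(c("well_id", "row", "col", "cq", "endpoint_fluorescence",
                      "status"), names(run$wells))
  utils::write.csv(run$wells[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Bulk qPCR replicate set
#'
#' Replicate Cq values for one gene at one template concentration, as
#' produced by a conventional (non-partitioned) qPCR run in triplicate.
#'
#' @param gene gene name
#' @param concentration template concentration (pg/uL or copies/uL)
#' @param cq_values numeric vector of replicate Cq values; `NA` marks a
#'   replicate with no amplification
#' @param max_cycles protocol cycle count (default 40)
#' @return object of class `bulk_qpcr`
#' @export
bulk_qpcr_replicates <- function(gene, concentration, cq_values, max_cycles = 40) {
  if (length(cq_values) < 1) stop("at least one replicate required", call. = FALSE)
  finite <- cq_values[!is.na(cq_values)]
  if (any(finite <= 0 | finite > max_cycles)) {
    stop("Cq values must lie in (0, max_cycles]", call. = FALSE)
  }
  structure(list(gene = gene, concentration = concentration,
                 cq_values = as.numeric(cq_values), max_cycles = max_cycles),
            class = "bulk_qpcr")
}

#' Read a bulk-qPCR replicate table
#'
#' CSV with columns `gene,concentration,replicate,cq`.
#'
#' @param path CSV path
#' @return list of `bulk_qpcr` objects, one per gene x concentration
#' @export
read_bulk_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("gene", "concentration", "replicate", "cq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("bulk-qPCR CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- interaction(df$gene, df$concentration, drop = TRUE)
  lapply(split(df, keys), function(g) {
    bulk_qpcr_replicates(g$gene[1], g$concentration[1], g$cq)
  })
}

#' Call wells positive/negative from Cq values
#'
#' A well is called positive when it reports a Cq at or below `max_cq`;
#' wells flagged `fail` (unfilled or bubbled) keep that status regardless of
#' any Cq value. When an NTC (no-template control) reference is supplied,
#' the mean positive count across the NTC run(s) is recorded on the returned
#' run as `n_dimer_expected` — the expected number of primer-dimer false
#' positives per chip.
#'
#' @param run a `chip_run`
#' @param max_cq positive-call threshold in cycles (default 40, the protocol
#'   cycle count)
#' @param ntc_reference a `chip_run` or list of `chip_run`s from no-template
#'   controls, or `NULL`
#' @return the re-called `chip_run`
#' @export
call_wells <- function(run, max_cq = 40, ntc_reference = NULL) {
  stopifnot(inherits(run, "chip_run"))
  w <- run$wells
  keep_fail <- w$status == "fail"
  w$status <- ifelse(!is.na(w$cq) & w$cq <= max_cq, "positive", "negative")
  w$status[keep_fail] <- "fail"
  w$cq[w$status == "negative"] <- NA_real_
  run$wells <- w
  if (!is.null(ntc_reference)) {
    ntcs <- if (inherits(ntc_reference, "chip_run")) list(ntc_reference) else ntc_reference
    k_ntc <- vapply(ntcs, function(r) {
      sum(!is.na(r$wells$cq) & r$wells$cq <= max_cq & r$wells$status != "fail")
    }, numeric(1))
    run$n_dimer_expected <- mean(k_ntc)
  }
  run
}

#' Summarize a chip run or bulk replicate set
#'
#' Returns positive/fail counts and the mean, sample standard deviation
#' (n - 1 denominator) and coefficient of variation (CV, percent) of the
#' positive-well Cq values. For a `bulk_qpcr` object the same summary is
#' computed over the replicate Cq values.
#'
#' @param run a `chip_run` or `bulk_qpcr`
#' @return object of class `run_summary`: list with `k_positive`, `n_fail`,
#'   `n_dimer_expected`, `mean_cq`, `sd_cq`, `cv_percent`
#' @export
summarize_run <- function(run) {
  if (inherits(run, "bulk_qpcr")) {
    cq <- run$cq_values[!is.na(run$cq_values)]
    k <- length(cq)
    n_fail <- 0L
    n_dimer <- NA_real_
  } else {
    stopifnot(inherits(run, "chip_run"))
    counts <- status_counts(run)
    pos <- run$wells$status %in% c("positive", "dimer")
    cq <- run$wells$cq[pos & !is.na(run$wells$cq)]
    k <- length(cq)
    n_fail <- counts[["fail"]]
    n_dimer <- if (is.null(run$n_dimer_expected)) NA_real_ else run$n_dimer_expected
  }
  if (k == 0) {
    out <- list(k_positive = 0L, n_fail = n_fail, n_dimer_expected = n_dimer,
                mean_cq = NA_real_, sd_cq = NA_real_, cv_percent = NA_real_)
  } else {
    m <- mean(cq)
    s <- if (k > 1) stats::sd(cq) else 0
    out <- list(k_positive = k, n_fail = n_fail, n_dimer_expected = n_dimer,
                mean_cq = m, sd_cq = s, cv_percent = 100 * s / m)
  }
  structure(out, class = "run_summary")
}

#' @export
print.chip_run <- function(x, ...) {
  counts <- status_counts(x)
  cat(sprintf("<chip_run> %d partitions: %d positive, %d negative, %d fail, %d dimer\n",
              x$n_partitions, counts[["positive"]], counts[["negative"]],
              counts[["fail"]], counts[["dimer"]]))
  if (length(x$metadata) > 0) {
    meta <- x$metadata[!vapply(x$metadata, is.null, logical(1))]
    cat("  metadata:", paste(names(meta), unlist(lapply(meta, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> k=%s fail=%s mean Cq=%.2f sd=%.3f CV=%.2f%%\n",
              format(x$k_positive), format(x$n_fail),
              x$mean_cq, x$sd_cq, x$cv_percent))
  invisible(x)
}
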