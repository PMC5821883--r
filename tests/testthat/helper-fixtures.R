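# In-code fixtures: small chip runs built directly from well tables.

# a chip run with the given positive-well Cq values, optional failed wells
# (with or without a Cq), everything else negative
make_run <- function(positive_cq = numeric(0), n = 2500, n_fail = 0,
                     fail_cq = NA_real_, metadata = list()) {
  grid <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  wells <- data.frame(
    well_id = sprintf("R%dC%d", idx %/% grid, idx %% grid),
    row = idx %/% grid, col = idx %% grid,
    cq = NA_real_, status = "negative", stringsAsFactors = FALSE)
  k <- length(positive_cq)
  if (k > 0) {
    wells$cq[seq_len(k)] <- positive_cq
    wells$status[seq_len(k)] <- "positive"
  }
  if (n_fail > 0) {
    i <- (k + 1):(k + n_fail)
    wells$status[i] <- "fail"
    wells$cq[i] <- fail_cq
  }
  chip_run(wells, n_partitions = n, metadata = metadata)
}
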