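# shared toy builders and independent oracles

toy_records <- function(n = 4, run_id = "toy", ...) {
  if (n == 0) return(toy_records(1, run_id, ...)[0, , drop = FALSE])
  rec <- data.frame(
    run_id = run_id,
    precursor_id = sprintf("PEP%03dK.2", seq_len(n)),
    stripped_sequence = sprintf("PEP%03dK", seq_len(n)),
    charge = 2L,
    measured_mz = 500 + seq_len(n),
    theoretical_mz = 500 + seq_len(n),
    apex_rt = seq_len(n),
    delta_rt = 0, fwhm = 0.1, peak_width = 0.25,
    missed_cleavages = 0,
    precursor_intensity = 1e6,
    peptide_intensity = 1e6,
    protein_group = sprintf("P%03d", seq_len(n)),
    protein_intensity = 1e6,
    q_value = 0.001, n_ms2_matched = 1,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (f in names(mods)) rec[[f]] <- mods[[f]]
  rec
}

toy_report <- function(n = 4, run_id = "toy", gradient_length = 30, ...) {
  ident_report(run_id, toy_records(n, run_id, ...), gradient_length)
}

# scan table with given number of cycles and windows, 1-s cycles
toy_scans <- function(n_cycles = 5, n_windows = 4, mz_lo = 400, width = 50,
                      run_id = "toy", tic1 = 1e9, cycle_s = 1) {
  W <- n_windows
  lo <- mz_lo + (seq_len(W) - 1) * width
  cyc <- rep(seq_len(n_cycles), each = W + 1)
  lev <- rep(c(1L, rep(2L, W)), n_cycles)
  rt <- (cyc - 1) * cycle_s / 60 +
    rep(c(0, seq_len(W) * cycle_s / 60 / (W + 1)), n_cycles)
  tic1 <- rep(tic1, length.out = n_cycles)
  scan_table(run_id, data.frame(
    scan_index = seq_along(cyc), ms_level = lev, rt = rt,
    tic = ifelse(lev == 1, tic1[cyc], tic1[cyc] / 20),
    base_peak_intensity = ifelse(lev == 1, 1e8, 5e6),
    peak_count = ifelse(lev == 1, 1000L, 150L),
    injection_time = ifelse(lev == 1, 20, 30),
    iso_lo = ifelse(lev == 1, NA_real_, rep(c(NA, lo), n_cycles)),
    iso_hi = ifelse(lev == 1, NA_real_, rep(c(NA, lo + width), n_cycles))))
}

write_report_tsv <- function(rec, path, headers = names(rec), sep = "\t") {
  names(rec) <- headers
  utils::write.table(rec, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# independent quantile-normalization oracle (complete matrices, no ties):
# reference = mean of order statistics; substitute by within-column order
oracle_quantile_normalize <- function(m) {
  ref <- sort(rowMeans(apply(m, 2, sort)))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# independent tree walker used to cross-check path lengths
oracle_path_length <- function(node, z) {
  depth <- 0
  while (!node$leaf) {
    node <- if (z[node$feature] < node$split) node$left else node$right
    depth <- depth + 1
  }
  depth + mscohort::iforest_cfactor(node$size)
}

# deterministic small random DIA run realised from random counts
random_counts_run <- function(seed) {
  set.seed(seed)
  W <- sample(3:6, 1)
  U <- sample(20:60, 1)
  k <- sample(1:3, U, replace = TRUE)
  R <- sum(k)
  # identified-scan budget compatible with the max duplicate span, with
  # headroom so every window can cover its identified cycles
  lo_i <- max(k) * min(W, U %/% 2)
  hi_i <- max(lo_i, floor(0.8 * R))
  I <- sample(lo_i:hi_i, 1)
  dia_run_from_counts(W, I, R, U, window_width = 10,
                      run_id = sprintf("rand%03d", seed))
}
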