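#' Assign identified precursors to MS2 scans
#'
#' For every precursor, finds the MS2 scans whose isolation window contains
#' its measured m/z and whose retention time lies within half a peak width of
#' the precursor apex.  When `n_ms2_matched` is available for a precursor,
#' the assignment is truncated to the `n_ms2_matched` scans nearest the apex
#' (ties broken by scan index), so the reconstructed redundancy equals the
#' reported per-precursor identified-scan count.
#'
#' @param report An `ident_report`.
#' @param scans A `scan_table`.
#' @return List of integer vectors (row indices into the MS2 subset of
#'   `scans$scans`), one per precursor record.
#' @keywords internal
assign_precursors_to_scans <- function(report, scans) {
  s <- scans$scans
  ms2 <- s[s$ms_level == 2, , drop = FALSE]
  win <- isolation_windows(scans)
  rec <- report$records
  out <- vector("list", nrow(rec))
  if (!nrow(ms2) || !nrow(rec)) return(out)
  # window id per MS2 scan
  wkey <- paste(ms2$iso_lo, ms2$iso_hi)
  wid <- match(wkey, paste(win$iso_lo, win$iso_hi))
  by_win <- split(seq_len(nrow(ms2)), wid)
  for (i in seq_len(nrow(rec))) {
    mz <- rec$measured_mz[i]
    w <- which(win$iso_lo <= mz & mz < win$iso_hi)
    if (!length(w)) next
    idx <- by_win[[as.character(w[1L])]]
    if (is.null(idx)) next
    pw <- rec$peak_width[i]
    if (is.na(pw)) pw <- 2 * max(diff(range(ms2$rt)) / max(1, nrow(ms2)), 0.01)
    d <- abs(ms2$rt[idx] - rec$apex_rt[i])
    cand <- idx[d <= pw / 2]
    if (!length(cand)) next
    k <- rec$n_ms2_matched[i]
    if (!is.na(k) && k >= 1 && k < length(cand)) {
      dc <- abs(ms2$rt[cand] - rec$apex_rt[i])
      cand <- cand[order(dc, cand)][seq_len(k)]
    }
    out[[i]] <- cand
  }
  out
}

#' Decompose a DIA run into the factors of the DIA scoring model
#'
#' The DIA scoring model factorises the number of identified precursors as
#' \deqn{N_{unique} = N_{acquired\,MS2} \times Q_{MS2} \times
#'   (complexity / duplicate\ rate)}
#' where `Q_MS2` is the fraction of acquired MS2 scans that yielded at least
#' one identification, the spectra complexity is redundant precursor
#' identifications per identified MS2 scan, the duplicate-identification
#' rate is redundant identifications per unique precursor, and their ratio
#' is the utilization rate of the MS2 scans (unique precursors per
#' identified MS2 scan).
#'
#' @param report An `ident_report` with `n_ms2_matched` populated (or a peak
#'   width per record so the scan assignment can be reconstructed).
#' @param scans A `scan_table` with at least one MS2 scan.
#' @return A `dia_decomposition` with fields `n_acquired_ms2`,
#'   `n_identified_ms2`, `q_ms2`, `n_redundant_precursors`,
#'   `n_unique_precursors`, `spectra_complexity`, `dup_rate`, `utilization`.
#' @examples
#' fx <- worked_example_fixture("win80")
#' decompose_dia_score(fx$report, fx$scans)   # utilization 1.44
#' @export
decompose_dia_score <- function(report, scans) {
  s <- scans$scans
  n_acq <- sum(s$ms_level == 2)
  if (n_acq == 0) stop("scan table contains no MS2 scans")
  if (!nrow(report$records)) stop("identification report is empty")
  asg <- assign_precursors_to_scans(report, scans)
  sizes <- lengths(asg)
  n_red <- sum(sizes)
  n_ident <- length(unique(unlist(asg)))
  n_uni <- sum(sizes > 0)
  q <- n_ident / n_acq
  cx <- if (n_ident > 0) n_red / n_ident else NA_real_
  dup <- if (n_uni > 0) n_red / n_uni else NA_real_
  util <- if (n_ident > 0) n_uni / n_ident else NA_real_
  structure(list(n_acquired_ms2 = n_acq, n_identified_ms2 = n_ident,
                 q_ms2 = q, n_redundant_precursors = n_red,
                 n_unique_precursors = n_uni, spectra_complexity = cx,
                 dup_rate = dup, utilization = util),
            class = "dia_decomposition")
}

#' @export
print.dia_decomposition <- function(x, ...) {
  cat("<dia_decomposition>\n")
  cat(sprintf("  acquired MS2 scans      %d\n", x$n_acquired_ms2))
  cat(sprintf("  identified MS2 scans    %d  (Q_MS2 = %.3f)\n",
              x$n_identified_ms2, x$q_ms2))
  cat(sprintf("  redundant precursor IDs %d\n", x$n_redundant_precursors))
  cat(sprintf("  unique precursors       %d\n", x$n_unique_precursors))
  cat(sprintf("  spectra complexity      %.2f\n", x$spectra_complexity))
  cat(sprintf("  duplicate-ID rate       %.2f\n", x$dup_rate))
  cat(sprintf("  MS2 utilization rate    %.2f\n", x$utilization))
  invisible(x)
}

#' Decompose a DDA run into the factors of the DDA scoring model
#'
#' \deqn{N_{unique} = N_{acquired\,MS2} \times Q_{MS2} \times
#'   P_{MS2\,per\,precursor}}
#' where `P` is unique precursors per identified MS2 scan.  In DDA each MS2
#' scan identifies at most one precursor, so the identified-scan count is
#' the sum of per-precursor `n_ms2_matched` (1 per record unless a precursor
#' was re-triggered).
#'
#' @inheritParams decompose_dia_score
#' @return A `dda_decomposition` with `n_acquired_ms2`, `n_identified_ms2`,
#'   `q_ms2`, `p_ms2_per_precursor`, `n_unique_precursors`, and a
#'   `computable` flag (FALSE when no MS2 scan was identified).
#' @export
decompose_dda_score <- function(report, scans) {
  s <- scans$scans
  n_acq <- sum(s$ms_level == 2)
  if (n_acq == 0) stop("scan table contains no MS2 scans")
  k <- report$records$n_ms2_matched
  k[is.na(k)] <- 1
  n_ident <- sum(k)
  n_uni <- nrow(report$records)
  structure(list(n_acquired_ms2 = n_acq, n_identified_ms2 = n_ident,
                 q_ms2 = n_ident / n_acq,
                 p_ms2_per_precursor = if (n_ident > 0) n_uni / n_ident
                                       else NA_real_,
                 n_unique_precursors = n_uni,
                 computable = n_ident > 0),
            class = "dda_decomposition")
}

#' @export
print.dda_decomposition <- function(x, ...) {
  cat(sprintf("<dda_decomposition> acquired %d, identified %d (Q_MS2 %.3f), unique %d (P %.3f)\n",
              x$n_acquired_ms2, x$n_identified_ms2, x$q_ms2,
              x$n_unique_precursors, x$p_ms2_per_precursor))
  invisible(x)
}

#' Scan-level metrics of one run
#'
#' MS1/MS2 scan counts, cycle time, ion injection time, the fraction of
#' scans filled to (within 1% of) the maximum injection time, peak counts,
#' base-peak intensities (log10), MS1 TIC coefficient of variation, and the
#' count of adjacent-MS1 TIC jumps beyond 10-fold (an ion-source stability
#' indicator).
#'
#' @param scans A `scan_table`.
#' @param jump_ratio Adjacent-TIC ratio beyond which a jump is counted.
#' @return Data frame of metric rows (`run_id, metric_id, value, unit,
#'   category, computable, reason`).
#' @export
compute_scan_metrics <- function(scans, jump_ratio = 10) {
  s <- scans$scans
  rid <- scans$run_id
  m1 <- s[s$ms_level == 1, , drop = FALSE]
  m2 <- s[s$ms_level == 2, , drop = FALSE]
  rows <- list(
    .metric_row(rid, "n_ms1_scans", nrow(m1), "count", "ms_signal"),
    .metric_row(rid, "n_ms2_scans", nrow(m2), "count", "ms_signal"))
  if (nrow(m1) >= 2) {
    rows <- c(rows, list(.metric_row(rid, "median_cycle_time",
                                     stats::median(diff(m1$rt)) * 60,
                                     "s", "ms_signal")))
  } else {
    rows <- c(rows, list(.na_metric(rid, "median_cycle_time", "s",
                                    "ms_signal", "fewer than 2 cycles")))
  }
  med_or_na <- function(id, x, unit, cat, f = identity) {
    x <- x[!is.na(x)]
    if (length(x)) .metric_row(rid, id, f(stats::median(x)), unit, cat)
    else .na_metric(rid, id, unit, cat, "no data")
  }
  rows <- c(rows, list(
    med_or_na("median_injection_time_ms1", m1$injection_time, "ms", "ms_signal"),
    med_or_na("median_injection_time_ms2", m2$injection_time, "ms", "ms_signal"),
    med_or_na("median_peak_count_ms1", m1$peak_count, "count", "ms_signal"),
    med_or_na("median_peak_count_ms2", m2$peak_count, "count", "ms_signal"),
    med_or_na("median_base_peak_intensity_ms1",
              m1$base_peak_intensity[m1$base_peak_intensity > 0],
              "log10", "ms_signal", log10),
    med_or_na("median_base_peak_intensity_ms2",
              m2$base_peak_intensity[m2$base_peak_intensity > 0],
              "log10", "ms_signal", log10)))
  it <- s$injection_time[!is.na(s$injection_time)]
  if (length(it) && max(it) > 0) {
    rows <- c(rows, list(.metric_row(rid, "fraction_scans_at_max_fill",
                                     mean(it >= 0.99 * max(it)),
                                     "fraction", "ms_signal")))
  } else {
    rows <- c(rows, list(.na_metric(rid, "fraction_scans_at_max_fill",
                                    "fraction", "ms_signal",
                                    "no injection times")))
  }
  tic <- m1$tic
  if (length(tic) >= 2 && mean(tic) > 0) {
    cv <- 100 * stats::sd(tic) / mean(tic)
    r <- tic[-1] / tic[-length(tic)]
    jumps <- sum(r > jump_ratio | r < 1 / jump_ratio, na.rm = TRUE)
    rows <- c(rows, list(
      .metric_row(rid, "tic_cv", cv, "%", "ion_source"),
      .metric_row(rid, "tic_jump_count", jumps, "count", "ion_source")))
  } else {
    rows <- c(rows, list(
      .na_metric(rid, "tic_cv", "%", "ion_source", "insufficient MS1 TIC"),
      .na_metric(rid, "tic_jump_count", "count", "ion_source",
                 "insufficient MS1 TIC")))
  }
  do.call(rbind, rows)
}

#' Identification-level metrics of one run
#'
#' Counts at precursor/peptide/protein-group level, missed-cleavage rate,
#' chromatographic peak width and FWHM medians, MS1 mass accuracy (ppm),
#' precursor intensity, protein-intensity dynamic range, and (when a
#' protein sequence database is supplied) mean protein sequence coverage.
#'
#' @param report An `ident_report`.
#' @param protein_db Optional named character vector of protein sequences
#'   keyed by accession, used for sequence coverage.
#' @return Data frame of metric rows.
#' @export
compute_ident_metrics <- function(report, protein_db = NULL) {
  r <- report$records
  rid <- report$run_id
  if (!nrow(r)) {
    ids <- c("n_precursors", "n_peptides", "n_protein_groups",
             "missed_cleavage_rate", "median_peak_width", "median_fwhm",
             "median_ms1_mass_accuracy", "median_log10_precursor_intensity",
             "intensity_dynamic_range", "mean_protein_sequence_coverage")
    return(do.call(rbind, lapply(ids, function(i)
      .na_metric(rid, i, "", "identification", "empty report"))))
  }
  rows <- list(
    .metric_row(rid, "n_precursors", nrow(r), "count", "identification"),
    .metric_row(rid, "n_peptides", length(unique(r$stripped_sequence)),
                "count", "identification"),
    .metric_row(rid, "n_protein_groups", length(unique(r$protein_group)),
                "count", "identification"))
  mc <- r$missed_cleavages
  rows <- c(rows, list(
    if (all(is.na(mc)))
      .na_metric(rid, "missed_cleavage_rate", "%", "sample",
                 "missed cleavages absent")
    else .metric_row(rid, "missed_cleavage_rate",
                     100 * mean(mc >= 1, na.rm = TRUE), "%", "sample")))
  med_or_na <- function(id, x, unit, cat, f = identity) {
    x <- x[!is.na(x)]
    if (length(x)) .metric_row(rid, id, f(stats::median(x)), unit, cat)
    else .na_metric(rid, id, unit, cat, "field absent")
  }
  rows <- c(rows, list(
    med_or_na("median_peak_width", r$peak_width, "min", "chromatography"),
    med_or_na("median_fwhm", r$fwhm, "min", "chromatography"),
    med_or_na("median_ms1_mass_accuracy",
              abs(r$measured_mz - r$theoretical_mz) / r$theoretical_mz * 1e6,
              "ppm", "ms_signal"),
    med_or_na("median_log10_precursor_intensity",
              r$precursor_intensity[r$precursor_intensity > 0],
              "log10", "ms_signal", log10)))
  pg <- r[!duplicated(r$protein_group), c("protein_group", "protein_intensity")]
  pint <- pg$protein_intensity[!is.na(pg$protein_intensity) &
                                 pg$protein_intensity > 0]
  rows <- c(rows, list(
    if (length(pint) >= 2) {
      q <- stats::quantile(pint, c(0.01, 0.99), names = FALSE)
      .metric_row(rid, "intensity_dynamic_range", log10(q[2] / q[1]),
                  "log10", "identification")
    } else .na_metric(rid, "intensity_dynamic_range", "log10",
                      "identification", "too few protein intensities")))
  rows <- c(rows, list(
    if (is.null(protein_db))
      .na_metric(rid, "mean_protein_sequence_coverage", "%",
                 "identification", "no sequence database supplied")
    else .metric_row(rid, "mean_protein_sequence_coverage",
                     .mean_coverage(r, protein_db), "%", "identification")))
  do.call(rbind, rows)
}

# mean % of residues covered by identified peptides, over db proteins seen
.mean_coverage <- function(rec, db) {
  accs <- unique(unlist(strsplit(rec$protein_group, ";", fixed = TRUE)))
  accs <- intersect(accs, names(db))
  if (!length(accs)) return(NA_real_)
  peps <- unique(rec$stripped_sequence)
  cov <- vapply(accs, function(a) {
    seqc <- db[[a]]
    hit <- rep(FALSE, nchar(seqc))
    for (p in peps) {
      m <- gregexpr(p, seqc, fixed = TRUE)[[1L]]
      if (m[1L] > 0)
        for (st in m) hit[st:(st + nchar(p) - 1L)] <- TRUE
    }
    100 * mean(hit)
  }, numeric(1))
  mean(cov)
}

#' Chromatography metrics of one run
#'
#' LC delay time (time from run start until a small fraction of cumulative
#' identifications has eluted; the "invalid acquiring time"), LC tail time,
#' the active-gradient fraction, and an identifications-per-minute histogram
#' (attached as attribute `rt_histogram`).
#'
#' @param report An `ident_report` (with `gradient_length`).
#' @param edge_quantile Cumulative-identification quantile defining the
#'   delay/tail boundaries; default 0.005 (0.5%).
#' @return Data frame of metric rows, with attribute `rt_histogram`.
#' @export
compute_chromatography_metrics <- function(report, edge_quantile = 0.005) {
  rid <- report$run_id
  rt <- report$records$apex_rt
  rt <- rt[!is.na(rt)]
  g <- report$gradient_length
  if (!length(rt) || is.na(g)) {
    out <- do.call(rbind, lapply(
      c("lc_delay_time", "lc_tail_time", "active_gradient_fraction"),
      function(i) .na_metric(rid, i, "min", "chromatography",
                             if (!length(rt)) "empty report"
                             else "gradient length unknown")))
    attr(out, "rt_histogram") <- NULL
    return(out)
  }
  qs <- stats::quantile(rt, c(edge_quantile, 1 - edge_quantile), names = FALSE)
  out <- rbind(
    .metric_row(rid, "lc_delay_time", qs[1], "min", "chromatography"),
    .metric_row(rid, "lc_tail_time", max(g - qs[2], 0), "min",
                "chromatography"),
    .metric_row(rid, "active_gradient_fraction",
                max(min((qs[2] - qs[1]) / g, 1), 0), "fraction",
                "chromatography"))
  br <- seq(0, ceiling(max(g, max(rt))), by = 1)
  h <- graphics::hist(rt, breaks = br, plot = FALSE)
  attr(out, "rt_histogram") <- data.frame(rt_bin_start = h$breaks[-length(h$breaks)],
                                          n_identifications = h$counts)
  out
}

#' DIA isolation-window metrics of one run
#'
#' Window count per cycle, mean window width, the distribution of precursors
#' over windows (by containment of the measured m/z; attribute
#' `per_window_counts`) and the window load imbalance (max/median per-window
#' precursor count).
#'
#' @param scans A `scan_table`.
#' @param report An `ident_report`.
#' @return Data frame of metric rows with attribute `per_window_counts`.
#' @export
compute_window_metrics <- function(scans, report) {
  rid <- scans$run_id
  win <- isolation_windows(scans)
  if (!nrow(win)) {
    out <- do.call(rbind, lapply(
      c("n_windows_per_cycle", "mean_window_width", "window_load_imbalance"),
      function(i) .na_metric(rid, i, "", "dia_windows", "no MS2 windows")))
    return(out)
  }
  s <- scans$scans
  per_cycle <- tapply(s$ms_level == 2, s$cycle, sum)
  nw <- as.numeric(names(sort(table(per_cycle), decreasing = TRUE))[1L])
  mz <- report$records$measured_mz
  cnt <- vapply(seq_len(nrow(win)), function(w)
    sum(!is.na(mz) & mz >= win$iso_lo[w] & mz < win$iso_hi[w]), numeric(1))
  imb <- if (stats::median(cnt) > 0) max(cnt) / stats::median(cnt) else NA_real_
  out <- rbind(
    .metric_row(rid, "n_windows_per_cycle", nw, "count", "dia_windows"),
    .metric_row(rid, "mean_window_width", mean(win$iso_hi - win$iso_lo),
                "Th", "dia_windows"),
    if (is.na(imb))
      .na_metric(rid, "window_load_imbalance", "ratio", "dia_windows",
                 "median per-window count is zero")
    else .metric_row(rid, "window_load_imbalance", imb, "ratio", "dia_windows"))
  attr(out, "per_window_counts") <- cbind(win, n_precursors = cnt)
  out
}

#' Detect MS1 features by centroid trace linking
#'
#' Links centroids of consecutive MS1 scans whose m/z agree within a ppm
#' tolerance into elution traces (a deliberately simple greedy chain builder
#' without isotope deconvolution), keeps traces spanning at least
#' `min_trace_length` scans, and marks a feature identified when some report
#' record matches it in m/z (ppm tolerance) and apex RT.
#'
#' @param scans A `scan_table` carrying MS1 centroids.
#' @param report An `ident_report`.
#' @param ppm_tol Matching tolerance in ppm (default 10).
#' @param min_trace_length Minimum scans per feature (default 3).
#' @return List with `features` (data frame `mz_centroid, rt_start, rt_end,
#'   apex_intensity, n_scans, identified`) and
#'   `identified_feature_fraction`.
#' @export
detect_ms1_features <- function(scans, report, ppm_tol = 10,
                                min_trace_length = 3) {
  cen <- scans$centroids
  if (is.null(cen) || !nrow(cen))
    stop("no MS1 centroids available: feature detection not computable")
  s <- scans$scans
  m1 <- s[s$ms_level == 1, , drop = FALSE]
  open <- list()   # each: mz, mzs, ints, rts
  done <- list()
  for (i in seq_len(nrow(m1))) {
    si <- m1$scan_index[i]; rt <- m1$rt[i]
    pk <- cen[cen$scan_index == si, , drop = FALSE]
    used <- rep(FALSE, nrow(pk))
    extended <- rep(FALSE, length(open))
    if (length(open) && nrow(pk)) {
      for (j in seq_along(open)) {
        dmz <- abs(pk$mz - open[[j]]$mz) / open[[j]]$mz * 1e6
        cand <- which(!used & dmz <= ppm_tol)
        if (length(cand)) {
          b <- cand[which.min(dmz[cand])]
          used[b] <- TRUE
          open[[j]]$mzs <- c(open[[j]]$mzs, pk$mz[b])
          open[[j]]$ints <- c(open[[j]]$ints, pk$intensity[b])
          open[[j]]$rts <- c(open[[j]]$rts, rt)
          open[[j]]$mz <- stats::weighted.mean(open[[j]]$mzs, open[[j]]$ints)
          extended[j] <- TRUE
        }
      }
    }
    done <- c(done, open[!extended])
    open <- open[extended]
    if (nrow(pk) && any(!used)) {
      for (b in which(!used))
        open <- c(open, list(list(mz = pk$mz[b], mzs = pk$mz[b],
                                  ints = pk$intensity[b], rts = rt)))
    }
  }
  done <- c(done, open)
  done <- Filter(function(t) length(t$rts) >= min_trace_length, done)
  if (!length(done))
    return(list(features = data.frame(), identified_feature_fraction = NA_real_))
  feats <- do.call(rbind, lapply(done, function(t)
    data.frame(mz_centroid = t$mz, rt_start = min(t$rts), rt_end = max(t$rts),
               apex_intensity = max(t$ints), n_scans = length(t$rts))))
  rec <- report$records
  feats$identified <- vapply(seq_len(nrow(feats)), function(i) {
    dppm <- abs(rec$measured_mz - feats$mz_centroid[i]) /
      feats$mz_centroid[i] * 1e6
    any(dppm <= ppm_tol & rec$apex_rt >= feats$rt_start[i] &
          rec$apex_rt <= feats$rt_end[i], na.rm = TRUE)
  }, logical(1))
  list(features = feats,
       identified_feature_fraction = mean(feats$identified))
}

#' Full intra-experiment metric extraction
#'
#' Convenience wrapper running scan, identification, chromatography and
#' window metrics plus the acquisition-mode decomposition for one run.
#'
#' @param report An `ident_report`.
#' @param scans A `scan_table`, or `NULL` (scan-dependent metrics are then
#'   reported as non-computable).
#' @param mode `"dia"` or `"dda"`.
#' @return List with `metrics` (data frame) and `decomposition`.
#' @export
compute_intra_metrics <- function(report, scans = NULL,
                                  mode = c("dia", "dda")) {
  mode <- match.arg(mode)
  rid <- report$run_id
  parts <- list(compute_ident_metrics(report),
                compute_chromatography_metrics(report))
  if (!is.null(scans)) {
    parts <- c(parts, list(compute_scan_metrics(scans),
                           compute_window_metrics(scans, report)))
  } else {
    parts <- c(parts, list(
      .na_metric(rid, "n_ms1_scans", "count", "ms_signal", "no scan table"),
      .na_metric(rid, "n_ms2_scans", "count", "ms_signal", "no scan table")))
  }
  dec <- NULL
  if (!is.null(scans) && nrow(report$records)) {
    dec <- if (mode == "dia") decompose_dia_score(report, scans)
           else decompose_dda_score(report, scans)
    parts <- c(parts, list(
      .metric_row(rid, "q_ms2", dec$q_ms2, "fraction", "identification"),
      .metric_row(rid, "n_acquired_ms2", dec$n_acquired_ms2, "count",
                  "ms_signal")))
    if (mode == "dia")
      parts <- c(parts, list(
        .metric_row(rid, "spectra_complexity", dec$spectra_complexity,
                    "ratio", "dia_windows"),
        .metric_row(rid, "dup_rate", dec$dup_rate, "ratio", "dia_windows"),
        .metric_row(rid, "ms2_utilization", dec$utilization, "ratio",
                    "identification")))
  }
  list(metrics = do.call(rbind, parts), decomposition = dec)
}
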