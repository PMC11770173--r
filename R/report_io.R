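#' Canonical identification-report fields
#'
#' Column names of the canonical per-run identification/quantification report
#' dialect.  Vendor reports with other headers are adapted through a
#' [column_map()].
#'
#' @return Character vector of canonical field names.
#' @export
ident_report_fields <- function() {
  c("run_id", "precursor_id", "stripped_sequence", "charge",
    "measured_mz", "theoretical_mz", "apex_rt", "delta_rt", "fwhm",
    "peak_width", "missed_cleavages", "precursor_intensity",
    "peptide_intensity", "protein_group", "protein_intensity",
    "q_value", "n_ms2_matched")
}

# fields that may be entirely absent / NA without invalidating a row
.optional_ident_fields <- c("delta_rt", "fwhm", "peak_width", "n_ms2_matched",
                            "peptide_intensity", "protein_intensity")

#' Describe a report column dialect
#'
#' Maps canonical field names to the source file's header names and records
#' the delimiter, decimal convention and retention-time unit.  Retention
#' times are always minutes internally; declare `rt_unit = "seconds"` to have
#' the reader convert.
#'
#' @param mapping Named character vector, names are canonical fields
#'   (see [ident_report_fields()]), values are source header names.  Fields
#'   not mentioned keep their canonical name.
#' @param delimiter Field delimiter, default tab.
#' @param decimal Decimal mark, `"."` or `","`.
#' @param rt_unit Unit of RT-like columns in the source file.
#' @return A `column_map` object.
#' @export
column_map <- function(mapping = character(), delimiter = "\t",
                       decimal = c(".", ","),
                       rt_unit = c("minutes", "seconds")) {
  decimal <- match.arg(decimal)
  rt_unit <- match.arg(rt_unit)
  mapping <- unlist(mapping)
  bad <- setdiff(names(mapping), ident_report_fields())
  if (length(bad))
    stop("unknown canonical field(s) in column map: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(names(mapping)))
    stop("each canonical field may be mapped at most once")
  full <- stats::setNames(ident_report_fields(), ident_report_fields())
  full[names(mapping)] <- mapping
  structure(list(mapping = full, delimiter = delimiter,
                 decimal = decimal, rt_unit = rt_unit),
            class = "column_map")
}

.read_delim <- function(path, delimiter, decimal) {
  utils::read.table(path, header = TRUE, sep = delimiter, dec = decimal,
                    quote = "\"", comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a per-run identification report
#'
#' Reads a delimited identification/quantification report (one row per
#' precursor), applies the column map, validates every row against the field
#' invariants and drops (and counts) rows that fail.
#'
#' Validation drops rows with: non-positive charge, negative retention time,
#' `q_value` outside \[0, 1\], negative intensities, `fwhm > peak_width`,
#' negative missed-cleavage or MS2-match counts, or a duplicated
#' `precursor_id` (first occurrence kept).
#'
#' @param path Path to the report file.
#' @param col_map A [column_map()]; default assumes canonical headers.
#' @param run_id Run identifier; default taken from the file's `run_id`
#'   column, falling back to the file name.
#' @param gradient_length Gradient length in minutes; default the ceiling of
#'   the largest apex RT.
#' @return An `ident_report`: list with `run_id`, `records` (data frame in
#'   canonical columns), `gradient_length` and attribute `n_dropped`.
#' @export
read_ident_report <- function(path, col_map = column_map(), run_id = NULL,
                              gradient_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    stop("empty file (no header): ", path)
  raw <- .read_delim(path, col_map$delimiter, col_map$decimal)
  required <- setdiff(ident_report_fields(), c(.optional_ident_fields, "run_id"))
  src <- col_map$mapping
  missing <- required[!src[required] %in% names(raw)]
  if (length(missing))
    stop("missing required column(s): ",
         paste(sprintf("%s (source header '%s')", missing, src[missing]),
               collapse = ", "))
  # assemble canonical frame
  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in ident_report_fields()) {
    h <- src[[f]]
    rec[[f]] <- if (h %in% names(raw)) raw[[h]] else NA
  }
  num <- setdiff(ident_report_fields(),
                 c("run_id", "precursor_id", "stripped_sequence",
                   "protein_group"))
  for (f in num) rec[[f]] <- suppressWarnings(as.numeric(rec[[f]]))
  if (col_map$rt_unit == "seconds") {
    for (f in c("apex_rt", "delta_rt", "fwhm", "peak_width"))
      rec[[f]] <- rec[[f]] / 60
  }
  if (is.null(run_id)) {
    run_id <- if (nrow(rec) && !all(is.na(rec$run_id)))
      as.character(rec$run_id[1L])
    else tools::file_path_sans_ext(basename(path))
  }
  rec$run_id <- rep(run_id, length.out = nrow(rec))
  ok <- rep(TRUE, nrow(rec))
  ok <- ok & !is.na(rec$precursor_id) & !duplicated(rec$precursor_id)
  ok <- ok & !is.na(rec$charge) & rec$charge >= 1
  ok <- ok & !is.na(rec$apex_rt) & rec$apex_rt >= 0
  ok <- ok & !is.na(rec$q_value) & rec$q_value >= 0 & rec$q_value <= 1
  for (f in c("precursor_intensity", "peptide_intensity", "protein_intensity"))
    ok <- ok & (is.na(rec[[f]]) | rec[[f]] >= 0)
  ok <- ok & (is.na(rec$missed_cleavages) | rec$missed_cleavages >= 0)
  ok <- ok & (is.na(rec$n_ms2_matched) | rec$n_ms2_matched >= 0)
  both <- !is.na(rec$fwhm) & !is.na(rec$peak_width)
  ok <- ok & (!both | rec$fwhm <= rec$peak_width)
  dropped <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  rownames(rec) <- NULL
  if (is.null(gradient_length))
    gradient_length <- if (nrow(rec)) ceiling(max(rec$apex_rt)) else NA_real_
  ident_report(run_id, rec, gradient_length, n_dropped = dropped)
}

#' Construct an identification report object
#'
#' @param run_id Run identifier.
#' @param records Data frame with the canonical columns of
#'   [ident_report_fields()].
#' @param gradient_length Gradient length in minutes.
#' @param n_dropped Rows dropped during validation (bookkeeping).
#' @return An `ident_report` object.
#' @export
ident_report <- function(run_id, records, gradient_length = NA_real_,
                         n_dropped = 0L) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(ident_report_fields(), names(records))
  if (length(miss)) for (f in miss) records[[f]] <- NA
  records <- records[ident_report_fields()]
  records$run_id <- rep(run_id, length.out = nrow(records))
  structure(list(run_id = run_id, records = records,
                 gradient_length = gradient_length),
            n_dropped = as.integer(n_dropped), class = "ident_report")
}

#' @export
print.ident_report <- function(x, ...) {
  cat(sprintf("<ident_report> run '%s': %d precursors, %d peptides, %d protein groups\n",
              x$run_id, nrow(x$records),
              length(unique(x$records$stripped_sequence)),
              length(unique(x$records$protein_group))))
  if (!is.na(x$gradient_length))
    cat(sprintf("  gradient %.1f min; %d rows dropped at read\n",
                x$gradient_length, attr(x, "n_dropped") %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-scan acquisition table
#'
#' Reads the canonical tab-delimited scan table (one row per MS1/MS2 scan)
#' and segments it into acquisition cycles: a cycle is one MS1 scan plus all
#' following MS2 scans until the next MS1 scan.
#'
#' @param path Path to the scan table (TSV with headers `scan_index,
#'   ms_level, rt, tic, base_peak_intensity, peak_count, injection_time,
#'   iso_lo, iso_hi`).
#' @param centroid_path Optional sidecar TSV of MS1 centroids with headers
#'   `scan_index, mz, intensity`.
#' @param run_id Run identifier, default the file name.
#' @return A `scan_table`: list with `run_id`, `scans` (data frame with an
#'   added `cycle` column) and optional `centroids`.
#' @export
read_scan_table <- function(path, centroid_path = NULL, run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .read_delim(path, "\t", ".")
  need <- c("scan_index", "ms_level", "rt", "tic", "base_peak_intensity",
            "peak_count", "injection_time", "iso_lo", "iso_hi")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop("scan table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(run_id)) run_id <- tools::file_path_sans_ext(basename(path))
  cen <- NULL
  if (!is.null(centroid_path)) {
    cen <- .read_delim(centroid_path, "\t", ".")
    stopifnot(all(c("scan_index", "mz", "intensity") %in% names(cen)))
  }
  scan_table(run_id, sc[need], centroids = cen)
}

#' Construct a scan-table object
#'
#' Validates scan ordering (non-decreasing RT, MS2 scans only after an MS1
#' scan, isolation windows with `iso_lo < iso_hi`) and assigns cycle numbers.
#' A changing per-cycle isolation-window set triggers a warning, not an
#' error.
#'
#' @param run_id Run identifier.
#' @param scans Data frame of per-scan records.
#' @param centroids Optional data frame (`scan_index`, `mz`, `intensity`).
#' @return A `scan_table` object.
#' @export
scan_table <- function(run_id, scans, centroids = NULL) {
  stopifnot(is.data.frame(scans), nrow(scans) >= 1)
  o <- order(scans$scan_index)
  scans <- scans[o, , drop = FALSE]
  dec <- which(diff(scans$rt) < 0)
  if (length(dec))
    stop(sprintf("retention time decreases at scan_index %d",
                 scans$scan_index[dec[1L] + 1L]))
  if (scans$ms_level[1L] != 1)
    stop("MS2 scan before any MS1 scan (scan_index ",
         scans$scan_index[1L], ")")
  is2 <- scans$ms_level == 2
  if (any(is2 & (is.na(scans$iso_lo) | is.na(scans$iso_hi))))
    stop("MS2 scans must carry isolation window bounds")
  if (any(is2) && any(scans$iso_lo[is2] >= scans$iso_hi[is2]))
    stop("isolation window must satisfy iso_lo < iso_hi")
  scans$cycle <- cumsum(scans$ms_level == 1)
  rownames(scans) <- NULL
  # window-set constancy across cycles (warning only)
  if (any(is2)) {
    key <- paste(scans$iso_lo[is2], scans$iso_hi[is2])
    sets <- split(key, scans$cycle[is2])
    ref <- sets[[1L]]
    same <- vapply(sets, function(s) identical(sort(unique(s)),
                                               sort(unique(ref))), logical(1))
    if (!all(same))
      warning("isolation-window set differs across cycles (first at cycle ",
              names(sets)[which(!same)[1L]], ")")
  }
  structure(list(run_id = run_id, scans = scans, centroids = centroids),
            class = "scan_table")
}

#' @export
print.scan_table <- function(x, ...) {
  n1 <- sum(x$scans$ms_level == 1); n2 <- sum(x$scans$ms_level == 2)
  cat(sprintf("<scan_table> run '%s': %d MS1 + %d MS2 scans, %d cycles, RT %.2f-%.2f min\n",
              x$run_id, n1, n2, max(x$scans$cycle),
              min(x$scans$rt), max(x$scans$rt)))
  invisible(x)
}

#' Distinct isolation windows of a scan table
#'
#' @param scans A `scan_table`.
#' @return Data frame `window, iso_lo, iso_hi` sorted by `iso_lo`.
#' @export
isolation_windows <- function(scans) {
  s <- scans$scans
  w <- unique(s[s$ms_level == 2, c("iso_lo", "iso_hi")])
  if (!nrow(w)) return(data.frame(window = integer(), iso_lo = numeric(),
                                  iso_hi = numeric()))
  w <- w[order(w$iso_lo, w$iso_hi), , drop = FALSE]
  data.frame(window = seq_len(nrow(w)), iso_lo = w$iso_lo, iso_hi = w$iso_hi,
             row.names = NULL)
}

#' Write a metric table
#'
#' Writes one row per `(run_id, metric_id)` with value, score and flag as a
#' tab-delimited file.  Values survive a write/read round trip to 6
#' significant digits.
#'
#' @param metrics Data frame with at least `run_id`, `metric_id`, `value`;
#'   optional `score`, `flag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1)
  out <- data.frame(run_id = metrics$run_id, metric_id = metrics$metric_id,
                    value = .fmt6(metrics$value),
                    score = .fmt6(metrics$score %||% rep(NA_real_, nrow(metrics))),
                    flag = metrics$flag %||% rep(NA, nrow(metrics)))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write metric table to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

.fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", as.numeric(x)))

#' Read back a metric table written by [write_metric_table()]
#'
#' @param path Path to the file.
#' @return Data frame `run_id, metric_id, value, score, flag`.
#' @export
read_metric_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$value <- as.numeric(x$value)
  x$score <- as.numeric(x$score)
  x
}

# uniform container for metric rows
.metric_row <- function(run_id, metric_id, value, unit = "", category = "",
                        computable = TRUE, reason = "") {
  data.frame(run_id = run_id, metric_id = metric_id,
             value = as.numeric(value), unit = unit, category = category,
             computable = computable, reason = reason,
             stringsAsFactors = FALSE)
}

.na_metric <- function(run_id, metric_id, unit, category, reason) {
  .metric_row(run_id, metric_id, NA_real_, unit, category, FALSE, reason)
}
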