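#' Contaminant panels
#'
#' A contaminant panel is a named set of protein accessions / gene symbols
#' whose summed intensity fraction flags compromised samples (e.g. blood or
#' cell contamination of urine).  Members are uppercase-normalised.
#'
#' @param panel_id Panel identifier.
#' @param members Character vector of accessions/symbols.
#' @return A `contaminant_panel` object.
#' @export
contaminant_panel <- function(panel_id, members) {
  members <- toupper(unique(members))
  if (!length(members)) stop("panel '", panel_id, "' is empty")
  structure(list(panel_id = panel_id, members = members),
            class = "contaminant_panel")
}

#' Default contaminant panels
#'
#' Reads the editable panel config shipped with the package: erythrocyte
#' (haemoglobin subunits and red-cell markers), cellular debris (keratins
#' and abundant intracellular proteins) and serum high-abundance proteins.
#' These default member lists are package-curated and freely replaceable.
#'
#' @param path Path to a panels TSV (`panel_id`, `members` comma-separated).
#' @return Named list of [contaminant_panel()] objects.
#' @export
default_contaminant_panels <- function(path = system.file("extdata",
                                                          "contaminant_panels.tsv",
                                                          package = "mscohort")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  panels <- lapply(seq_len(nrow(tab)), function(i)
    contaminant_panel(tab$panel_id[i],
                      strsplit(tab$members[i], ",", fixed = TRUE)[[1L]]))
  stats::setNames(panels, tab$panel_id)
}

#' Contaminant intensity fraction of one run
#'
#' The summed intensity of protein groups containing at least one panel
#' member, divided by the total protein intensity of the run.
#'
#' @param report An `ident_report` with protein intensities.
#' @param panel A [contaminant_panel()].
#' @return Fraction in \[0, 1\], or `NA` when the total intensity is zero or
#'   absent.
#' @export
contaminant_fraction <- function(report, panel) {
  r <- report$records
  pg <- r[!duplicated(r$protein_group),
          c("protein_group", "protein_intensity"), drop = FALSE]
  pg <- pg[!is.na(pg$protein_intensity), , drop = FALSE]
  tot <- sum(pg$protein_intensity)
  if (!nrow(pg) || tot <= 0) return(NA_real_)
  hit <- vapply(strsplit(toupper(pg$protein_group), ";", fixed = TRUE),
                function(a) any(a %in% panel$members), logical(1))
  sum(pg$protein_intensity[hit]) / tot
}

#' Retention-time deviation metrics across a cohort
#'
#' Per run, the median absolute deltaRT (empirical minus library/predicted
#' RT).  Between every pair of runs, the mean squared error of apex RT over
#' precursors identified in both:
#' \deqn{MSE(i,j) = \frac{1}{n}\sum_k (RT_{i,k} - RT_{j,k})^2}
#' Pairs sharing fewer than `min_shared` precursors are non-computable
#' (`NA`).  The per-run mean of its MSE row (off-diagonal) is the second
#' RT metric.
#'
#' @param reports List of `ident_report` objects (>= 2).
#' @param min_shared Minimum shared precursors per pair (default 50).
#' @return List with `median_abs_delta_rt` (named vector), `rt_mse`
#'   (symmetric matrix, zero diagonal) and `mean_rt_mse` (named vector).
#' @export
rt_deviation_metrics <- function(reports, min_shared = 50) {
  stopifnot(length(reports) >= 2)
  ids <- vapply(reports, function(r) r$run_id, character(1))
  lc1 <- vapply(reports, function(r) {
    d <- abs(r$records$delta_rt)
    d <- d[!is.na(d)]
    if (length(d)) stats::median(d) else NA_real_
  }, numeric(1))
  names(lc1) <- ids
  n <- length(reports)
  mse <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(mse) <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- reports[[i]]$records; b <- reports[[j]]$records
    m <- match(a$precursor_id, b$precursor_id)
    ok <- !is.na(m)
    if (sum(ok) >= min_shared) {
      d <- a$apex_rt[ok] - b$apex_rt[m[ok]]
      mse[i, j] <- mse[j, i] <- mean(d^2)
    }
  }
  lc2 <- vapply(seq_len(n), function(i) {
    row <- mse[i, -i]
    if (all(is.na(row))) NA_real_ else mean(row, na.rm = TRUE)
  }, numeric(1))
  names(lc2) <- ids
  list(median_abs_delta_rt = lc1, rt_mse = mse, mean_rt_mse = lc2)
}

#' Build a cross-run log2 intensity matrix
#'
#' Rows are identifiers at the requested level (precursor id, stripped
#' peptide sequence, or protein group), columns are runs; cells are log2
#' intensities, `NA` when unobserved.  Duplicate identifiers within a run
#' (e.g. multiple precursors of one peptide) keep the maximum intensity.
#'
#' @param reports List of `ident_report` objects.
#' @param level `"precursor"`, `"peptide"` or `"protein"`.
#' @return Numeric matrix with identifier rownames and run colnames.
#' @export
build_intensity_matrix <- function(reports,
                                   level = c("precursor", "peptide",
                                             "protein")) {
  level <- match.arg(level)
  key_col <- switch(level, precursor = "precursor_id",
                    peptide = "stripped_sequence", protein = "protein_group")
  int_col <- switch(level, precursor = "precursor_intensity",
                    peptide = "peptide_intensity",
                    protein = "protein_intensity")
  ids <- vapply(reports, function(r) r$run_id, character(1))
  per_run <- lapply(reports, function(r) {
    rec <- r$records
    v <- rec[[int_col]]
    ok <- !is.na(v) & v > 0 & !is.na(rec[[key_col]])
    if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
    agg <- tapply(v[ok], rec[[key_col]][ok], max)
    stats::setNames(log2(as.numeric(agg)), names(agg))
  })
  keys <- sort(unique(unlist(lapply(per_run, names))))
  m <- matrix(NA_real_, length(keys), length(ids),
              dimnames = list(keys, ids))
  for (i in seq_along(per_run))
    m[names(per_run[[i]]), i] <- per_run[[i]]
  m
}

#' Robust standard deviation
#'
#' `1.4826 * median(|x - median(x)|)`, a consistent estimator of the SD
#' under normality.
#'
#' @param x Numeric vector (`NA` removed).
#' @return Robust SD.
#' @export
robust_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  1.4826 * stats::median(abs(x - stats::median(x)))
}

#' Intensity-distribution metrics at one rollup level
#'
#' The six per-run statistics of the cross-run intensity distribution:
#' identification count, median log2 intensity, interquartile range of log2
#' intensity, robust SD (1.4826 x MAD) of log2 intensity, the median of the
#' run's pairwise Pearson correlations of log2 intensity with every other
#' run (pairwise-complete on shared identifiers, minimum overlap
#' `min_shared`), and the median-shift normalization factor (cohort median
#' of per-run medians minus the run's median).  Applied at precursor,
#' peptide and protein level these are the 18 distribution metrics.
#'
#' @param reports List of `ident_report` objects.
#' @param level `"precursor"`, `"peptide"` or `"protein"`.
#' @param min_shared Minimum shared identifiers for a Pearson pair.
#' @return Data frame: one row per run, columns `run_id, n_ids,
#'   median_log2_intensity, iqr_log2_intensity, robust_sd_log2_intensity,
#'   median_pearson, norm_factor`.
#' @export
quant_distribution_metrics <- function(reports,
                                       level = c("precursor", "peptide",
                                                 "protein"),
                                       min_shared = 50) {
  level <- match.arg(level)
  m <- build_intensity_matrix(reports, level)
  n <- ncol(m)
  meds <- apply(m, 2, stats::median, na.rm = TRUE)
  cohort_med <- stats::median(meds, na.rm = TRUE)
  pear <- .median_pairwise_pearson(m, min_shared)
  data.frame(
    run_id = colnames(m),
    n_ids = apply(m, 2, function(x) sum(!is.na(x))),
    median_log2_intensity = meds,
    iqr_log2_intensity = apply(m, 2, stats::IQR, na.rm = TRUE),
    robust_sd_log2_intensity = apply(m, 2, robust_sd),
    median_pearson = pear,
    norm_factor = cohort_med - meds,
    row.names = NULL, stringsAsFactors = FALSE)
}

.median_pairwise_pearson <- function(m, min_shared) {
  n <- ncol(m)
  cc <- matrix(NA_real_, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) >= max(min_shared, 3))
        cc[i, j] <- cc[j, i] <- stats::cor(m[ok, i], m[ok, j])
    }
  }
  vapply(seq_len(n), function(i) {
    r <- cc[i, -i]
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE)
  }, numeric(1))
}

#' Inter-experiment metric catalogue
#'
#' The 23 cohort-level metric ids with their bad direction: 3 contaminant
#' panels (SP), 2 retention-time metrics (LC) and 6 distribution statistics
#' at 3 rollup levels (MS).  Directions: `bad_high` (larger is worse),
#' `bad_low` (smaller is worse), `bad_both` (deviation from the centre in
#' either direction is worse).
#'
#' @return Data frame `metric_id, direction`.
#' @export
inter_metric_catalogue <- function() {
  stat_dir <- c(n_ids = "bad_low", median_log2_intensity = "bad_low",
                iqr_log2_intensity = "bad_high",
                robust_sd_log2_intensity = "bad_high",
                median_pearson = "bad_low", norm_factor = "bad_both")
  rows <- list(data.frame(
    metric_id = c("sp_erythrocyte", "sp_cellular_debris",
                  "sp_serum_high_abundance",
                  "lc_median_abs_delta_rt", "lc_mean_rt_mse"),
    direction = c("bad_high", "bad_high", "bad_high",
                  "bad_high", "bad_high")))
  for (lv in c("precursor", "peptide", "protein"))
    rows <- c(rows, list(data.frame(
      metric_id = paste(lv, names(stat_dir), sep = "_"),
      direction = unname(stat_dir))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score cohort metric values by the 2-SD rule
#'
#' Per metric, centre = cohort median, spread = SD across runs.  Values on
#' the good side of the median score 5; on the bad side the score falls
#' linearly from 5 at the median to 1 at two SD, clamped at 1 beyond.  A
#' value more than two SD from the median in the bad direction is flagged.
#' For `bad_both` metrics both directions count as bad.  Zero spread gives
#' score 5 and no flag.
#'
#' @param values Numeric vector of one metric across runs.
#' @param direction `"bad_high"`, `"bad_low"` or `"bad_both"`.
#' @return List with `score` and `flag` vectors.
#' @export
score_inter_metric <- function(values, direction = c("bad_high", "bad_low",
                                                     "bad_both")) {
  direction <- match.arg(direction)
  ctr <- stats::median(values, na.rm = TRUE)
  sdv <- stats::sd(values, na.rm = TRUE)
  dev <- values - ctr
  bad <- switch(direction, bad_high = pmax(dev, 0),
                bad_low = pmax(-dev, 0), bad_both = abs(dev))
  if (is.na(sdv) || sdv == 0) {
    score <- ifelse(is.na(values), NA_real_, 5)
    flag <- ifelse(is.na(values), NA, FALSE)
  } else {
    score <- 5 - 4 * pmin(bad, 2 * sdv) / (2 * sdv)
    flag <- bad > 2 * sdv
  }
  list(score = score, flag = flag)
}

#' Assemble the cohort metric matrix
#'
#' Computes the 23 inter-experiment metrics for every run, the pairwise
#' matrices (RT MSE, Pearson correlation of log2 protein intensity), and
#' the 2-SD scores and flags.  With fewer than three runs the values are
#' still reported but scores and flags are suppressed.
#'
#' @param reports List of `ident_report` objects.
#' @param panels Named list of [contaminant_panel()] objects; default the
#'   shipped erythrocyte / cellular-debris / serum panels (SP1-SP3).
#' @param min_shared Minimum shared identifiers for pairwise statistics.
#' @return A `cohort_matrix`: list with `runs`, `values` (23 x n matrix),
#'   `scores`, `flags`, `directions`, `pairwise` (list of `rt_mse`,
#'   `pearson_log2_protein`).
#' @export
build_cohort_matrix <- function(reports,
                                panels = default_contaminant_panels(),
                                min_shared = 50) {
  stopifnot(length(reports) >= 2)
  ids <- vapply(reports, function(r) r$run_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate run_id in cohort")
  cat <- inter_metric_catalogue()
  vals <- matrix(NA_real_, nrow(cat), length(ids),
                 dimnames = list(cat$metric_id, ids))
  sp_ids <- c(erythrocyte = "sp_erythrocyte",
              cellular_debris = "sp_cellular_debris",
              serum_high_abundance = "sp_serum_high_abundance")
  for (p in names(sp_ids)) {
    if (!p %in% names(panels)) next
    vals[sp_ids[[p]], ] <- vapply(reports, contaminant_fraction,
                                  numeric(1), panel = panels[[p]])
  }
  rtm <- rt_deviation_metrics(reports, min_shared = min_shared)
  vals["lc_median_abs_delta_rt", ] <- rtm$median_abs_delta_rt
  vals["lc_mean_rt_mse", ] <- rtm$mean_rt_mse
  prot_mat <- NULL
  for (lv in c("precursor", "peptide", "protein")) {
    q <- quant_distribution_metrics(reports, lv, min_shared = min_shared)
    for (stat in c("n_ids", "median_log2_intensity", "iqr_log2_intensity",
                   "robust_sd_log2_intensity", "median_pearson",
                   "norm_factor"))
      vals[paste(lv, stat, sep = "_"), ] <- q[[stat]]
  }
  # pairwise protein-level Pearson matrix for the report bundle
  pm <- build_intensity_matrix(reports, "protein")
  n <- ncol(pm)
  pear <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(pear) <- 1
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(pm[, i]) & !is.na(pm[, j])
    if (sum(ok) >= max(min_shared, 3))
      pear[i, j] <- pear[j, i] <- stats::cor(pm[ok, i], pm[ok, j])
  }
  scores <- flags <- matrix(NA_real_, nrow(cat), length(ids),
                            dimnames = dimnames(vals))
  if (length(ids) >= 3) {
    for (k in seq_len(nrow(cat))) {
      sf <- score_inter_metric(vals[k, ], cat$direction[k])
      scores[k, ] <- sf$score
      flags[k, ] <- sf$flag
    }
  } else {
    warning("fewer than 3 runs: scores and flags suppressed")
  }
  structure(list(runs = ids, values = vals, scores = scores,
                 flags = flags == 1, directions = stats::setNames(
                   cat$direction, cat$metric_id),
                 pairwise = list(rt_mse = rtm$rt_mse,
                                 pearson_log2_protein = pear)),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d runs x %d inter-experiment metrics\n",
              length(x$runs), nrow(x$values)))
  nf <- colSums(x$flags, na.rm = TRUE)
  if (any(!is.na(x$flags))) {
    cat("  flagged metrics per run (2-SD rule):\n")
    print(nf)
  } else cat("  scores/flags suppressed (fewer than 3 runs)\n")
  invisible(x)
}

#' List low-quality runs by the flagged-metric rule
#'
#' Runs for which at least `min_flagged_metrics` of the 23 inter-experiment
#' metrics deviate by more than two SD from the cohort median in the bad
#' direction.
#'
#' @param matrix A `cohort_matrix`.
#' @param min_flagged_metrics Threshold (default 7).
#' @return Character vector of run ids (possibly empty), with attribute
#'   `n_flagged` (named counts for all runs).
#' @export
flag_low_quality <- function(matrix, min_flagged_metrics = 7) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  nf <- colSums(matrix$flags, na.rm = TRUE)
  out <- names(nf)[nf >= min_flagged_metrics & !is.na(nf)]
  attr(out, "n_flagged") <- nf
  out
}
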