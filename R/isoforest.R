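#' Average path-length normaliser c(m)
#'
#' Expected path length of an unsuccessful binary-search-tree query over
#' `m` points: `c(m) = 2 H(m-1) - 2 (m-1)/m`, with `c(1) = 0` and the
#' harmonic number computed exactly for small arguments (so `c(2) = 1`)
#' and by `ln(i) + gamma` beyond.
#'
#' @param m Number of points (vectorised).
#' @return Normaliser value(s).
#' @export
iforest_cfactor <- function(m) {
  vapply(m, function(mm) {
    if (mm <= 1) return(0)
    2 * .harmonic(mm - 1) - 2 * (mm - 1) / mm
  }, numeric(1))
}

.harmonic <- function(i) {
  if (i <= 256) sum(1 / seq_len(i))
  else log(i) + 0.5772156649015329
}

# recursively grow one isolation tree on rows of x
.grow_itree <- function(x, depth, limit) {
  n <- nrow(x)
  if (n <= 1 || depth >= limit)
    return(list(leaf = TRUE, size = n))
  rng <- apply(x, 2, range)
  usable <- which(rng[2, ] > rng[1, ])
  if (!length(usable))                       # duplicated rows
    return(list(leaf = TRUE, size = n))
  f <- if (length(usable) == 1) usable else sample(usable, 1L)
  sv <- stats::runif(1, rng[1, f], rng[2, f])
  left <- x[, f] < sv
  list(leaf = FALSE, feature = f, split = sv,
       left = .grow_itree(x[left, , drop = FALSE], depth + 1L, limit),
       right = .grow_itree(x[!left, , drop = FALSE], depth + 1L, limit))
}

.tree_depth <- function(node) {
  if (node$leaf) 0L
  else 1L + max(.tree_depth(node$left), .tree_depth(node$right))
}

.path_length <- function(node, x, depth = 0) {
  if (node$leaf) return(depth + iforest_cfactor(node$size))
  if (x[node$feature] < node$split) .path_length(node$left, x, depth + 1)
  else .path_length(node$right, x, depth + 1)
}

#' Fit an isolation forest on a cohort metric matrix
#'
#' Implements the original isolation-forest algorithm: each tree is grown
#' on a random subsample of size `psi` by recursive random single-feature
#' splits until points are isolated or the height limit `ceil(log2 psi)` is
#' reached.  Features are standardised to median/IQR beforehand (metrics
#' have wildly different units); constant features are dropped.
#'
#' @param x Numeric matrix, rows = runs, columns = metrics — e.g.
#'   `t(cohort$values)` from [build_cohort_matrix()].  Columns containing
#'   `NA` are dropped with a message.
#' @param n_trees Number of trees (default 100).
#' @param psi Subsample size (default `min(256, nrow(x))`).
#' @param seed Integer seed for reproducibility.
#' @return An `isolation_forest` model.
#' @export
fit_isolation_forest <- function(x, n_trees = 100,
                                 psi = min(256, nrow(x)), seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 3)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  has_na <- apply(x, 2, anyNA)
  if (any(has_na)) {
    message("dropping ", sum(has_na), " feature(s) with missing values")
    x <- x[, !has_na, drop = FALSE]
  }
  ctr <- apply(x, 2, stats::median)
  scl <- apply(x, 2, stats::IQR)
  # an IQR of zero does not mean constant: a single extreme value in an
  # otherwise identical column is exactly what must not be dropped
  rng <- apply(x, 2, function(v) diff(range(v)))
  scl[scl == 0] <- rng[scl == 0] / 2
  keep <- scl > 0
  if (!any(keep)) stop("all features are constant: nothing to isolate")
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  psi <- min(psi, nrow(z))
  limit <- ceiling(log2(psi))
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample.int(nrow(z), psi)
    .grow_itree(z[idx, , drop = FALSE], 0L, limit)
  })
  structure(list(trees = trees, psi = psi, n_trees = n_trees,
                 height_limit = limit, center = ctr[keep],
                 scale = scl[keep], features = colnames(z), seed = seed),
            class = "isolation_forest")
}

#' @export
print.isolation_forest <- function(x, ...) {
  cat(sprintf("<isolation_forest> %d trees, psi = %d, height limit %d, %d features\n",
              x$n_trees, x$psi, x$height_limit, length(x$features)))
  invisible(x)
}

#' Anomaly scores from an isolation forest
#'
#' Scores each run as `2^(-E(h)/c(psi))` where `E(h)` is the mean path
#' length over the trees (leaves of size `m` contribute the `c(m)`
#' adjustment).  Scores lie in (0, 1); short paths (easily isolated runs)
#' score high.
#'
#' The default cutoff is 0.5: a point whose average path length equals the
#' expectation for an unremarkable point scores exactly 0.5, so any score
#' above it means faster-than-average isolation (this is also the decision
#' level of the common library implementations' automatic contamination
#' setting).  On cohort-sized data scores concentrate near 0.5, so the raw
#' `is_outlier` column is deliberately sensitive; [detect_outliers()]
#' additionally requires deviating metrics to corroborate a call.
#'
#' @param model An `isolation_forest`.
#' @param x Matrix of runs x metrics on the original scale (the model's
#'   standardisation is applied); must contain the model's features.
#' @param threshold Score cutoff for the `is_outlier` column (default 0.5).
#' @return Data frame `run_id, anomaly_score, mean_path_length, is_outlier`,
#'   with the applied cutoff as attribute `threshold`.
#' @export
score_anomalies <- function(model, x, threshold = 0.5) {
  stopifnot(inherits(model, "isolation_forest"), is.matrix(x))
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  z <- sweep(sweep(x[, model$features, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  cpsi <- iforest_cfactor(model$psi)
  mpl <- vapply(seq_len(nrow(z)), function(i)
    mean(vapply(model$trees, .path_length, numeric(1), x = z[i, ])),
    numeric(1))
  score <- 2^(-mpl / cpsi)
  cut <- as.numeric(threshold)
  out <- data.frame(run_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    anomaly_score = score, mean_path_length = mpl,
                    is_outlier = score > cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- cut
  out
}

#' Detect outlier runs in a cohort
#'
#' Combines the isolation-forest calls with the runs reported by the 2-SD
#' flagged-metric rule ([flag_low_quality()]); the default policy is their
#' union, `"intersection"` requires both.  A forest call is only accepted
#' when at least `min_explained` of the run's 23 metrics are 2-SD-flagged,
#' so that every reported run can be annotated with the metrics that
#' deviate: an isolation that no metric corroborates is treated as noise of
#' the forest (on cohort-sized data anomaly scores crowd the 0.5 decision
#' level, so uncorroborated single calls are common).  These defaults are
#' calibrated on synthetic cohorts with planted anomalies and are plain
#' arguments.
#'
#' @param anomalies Data frame from [score_anomalies()].
#' @param matrix A `cohort_matrix`.
#' @param policy `"union"` or `"intersection"`.
#' @param min_flagged_metrics Threshold for the run-level 2-SD rule
#'   (default 7).
#' @param min_explained Minimum flagged metrics needed to corroborate a
#'   forest call (default 2; a single 2-SD flag arises too easily by
#'   chance).
#' @return Data frame ordered by decreasing anomaly score: `run_id,
#'   anomaly_score, n_flagged_metrics, flagged_metrics` (comma-separated).
#' @export
detect_outliers <- function(anomalies, matrix,
                            policy = c("union", "intersection"),
                            min_flagged_metrics = 7, min_explained = 2) {
  policy <- match.arg(policy)
  stopifnot(inherits(matrix, "cohort_matrix"))
  nfl <- colSums(matrix$flags, na.rm = TRUE)
  by_forest <- anomalies$run_id[anomalies$is_outlier &
                                  nfl[anomalies$run_id] >= min_explained]
  by_flags <- flag_low_quality(matrix, min_flagged_metrics)
  sel <- if (policy == "union") union(by_forest, by_flags)
         else intersect(by_forest, by_flags)
  nf <- colSums(matrix$flags, na.rm = TRUE)
  out <- data.frame(
    run_id = sel,
    anomaly_score = anomalies$anomaly_score[match(sel, anomalies$run_id)],
    n_flagged_metrics = as.integer(nf[sel]),
    flagged_metrics = vapply(sel, function(r) {
      f <- matrix$flags[, r]
      paste(rownames(matrix$flags)[!is.na(f) & f], collapse = ",")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$anomaly_score), , drop = FALSE]
}
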