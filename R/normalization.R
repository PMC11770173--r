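#' Median-shift normalization
#'
#' Shifts every column of a log2 intensity matrix so that its median equals
#' the cohort median of the pre-shift column medians.  The per-run shifts
#' are the normalization-factor metric.  Missing cells stay missing.
#'
#' @param m Numeric matrix (rows identifiers, columns runs, log2 scale).
#' @return List with `matrix` (normalized) and `shifts` (named vector).
#' @export
median_shift_normalize <- function(m) {
  stopifnot(is.matrix(m))
  meds <- apply(m, 2, stats::median, na.rm = TRUE)
  target <- stats::median(meds, na.rm = TRUE)
  shifts <- target - meds
  list(matrix = sweep(m, 2, shifts, "+"), shifts = shifts)
}

#' Pairwise-ratio (least-squares) shift normalization
#'
#' Estimates per-run additive log2 shifts from the median pairwise
#' log-ratios between runs, in the spirit of ratio-based label-free
#' quantification: shifts minimise the squared difference between the
#' observed median log-ratio of each run pair (on their shared identifiers)
#' and the shift difference, with the first run anchored at 0.  Robust to
#' missingness as long as the pair-overlap graph is connected.
#'
#' @param m Numeric matrix (log2 scale, `NA` allowed).
#' @param min_shared Minimum shared identifiers for a pair to contribute.
#' @return List with `matrix` and `shifts` (named, first run 0).
#' @export
pairwise_ratio_shift_normalize <- function(m, min_shared = 2) {
  stopifnot(is.matrix(m))
  n <- ncol(m)
  if (n < 2) stop("need at least two runs")
  pairs <- list(); ratios <- numeric()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) >= min_shared) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      ratios[length(ratios) + 1L] <- stats::median(m[ok, i] - m[ok, j])
    }
  }
  # connectivity of the overlap graph
  comp <- .components(n, pairs)
  if (max(comp) > 1) {
    groups <- split(colnames(m) %||% as.character(seq_len(n)), comp)
    stop("pair-overlap graph is disconnected; components: ",
         paste(vapply(groups, paste, character(1), collapse = ","),
               collapse = " | "))
  }
  # least squares for d_2..d_n with d_1 = 0, model r_ij = d_i - d_j
  A <- matrix(0, length(pairs), n - 1)
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    if (i > 1) A[k, i - 1] <- 1
    if (j > 1) A[k, j - 1] <- -1
  }
  d <- c(0, if (n > 1) stats::lm.fit(A, ratios)$coefficients else numeric(0))
  d[is.na(d)] <- 0
  shifts <- stats::setNames(-d, colnames(m))
  list(matrix = sweep(m, 2, shifts, "+"), shifts = shifts)
}

.components <- function(n, pairs) {
  comp <- seq_len(n)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (p in pairs) {
    adj[[p[1]]] <- c(adj[[p[1]]], p[2])
    adj[[p[2]]] <- c(adj[[p[2]]], p[1])
  }
  seen <- rep(FALSE, n); cid <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE; comp[v] <- cid
      queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
    }
  }
  comp
}

#' Quantile normalization
#'
#' Rows observed in every run (complete cases) define the reference
#' distribution as the mean of order statistics across runs.  Each column's
#' observed values are then mapped onto the reference by rank; tied values
#' receive the mean reference value of their tied ranks.  After
#' normalization, all columns restricted to complete rows have identical
#' sorted values.  Missing cells stay missing.
#'
#' @param m Numeric matrix (log2 scale, `NA` allowed).
#' @return Normalized matrix.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  cc <- stats::complete.cases(m)
  if (!any(cc)) stop("no complete rows to define the reference distribution")
  ref <- sort(rowMeans(apply(m[cc, , drop = FALSE], 2, sort)))
  nref <- length(ref)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- which(!is.na(m[, j]))
    nj <- length(obs)
    if (!nj) next
    x <- m[obs, j]
    ord <- order(x)
    # integer rank positions mapped onto the reference grid
    pos <- if (nj == 1) (nref + 1) / 2
           else 1 + (seq_len(nj) - 1) * (nref - 1) / (nj - 1)
    refv <- stats::approx(seq_len(nref), ref, xout = pos)$y
    newv <- numeric(nj)
    newv[ord] <- refv
    # ties: mean of the reference values assigned within each tie group
    if (anyDuplicated(x)) {
      tie_mean <- tapply(newv, x, mean)
      newv <- as.numeric(tie_mean[as.character(x)])
    }
    out[obs, j] <- newv
  }
  out
}

#' Apply a cross-run normalization by name
#'
#' Dispatcher used by the cohort pipeline: `"none"`, `"median"` (shift to
#' common median), `"pairwise"` (least-squares median-ratio shifts) or
#' `"quantile"`.
#'
#' @param m Numeric matrix (log2 scale).
#' @param method Method name.
#' @return List with `matrix` and (for shift methods) `shifts`.
#' @export
normalize_intensities <- function(m, method = c("none", "median",
                                                "pairwise", "quantile")) {
  method <- match.arg(method)
  switch(method,
         none = list(matrix = m, shifts = stats::setNames(
           rep(0, ncol(m)), colnames(m))),
         median = median_shift_normalize(m),
         pairwise = pairwise_ratio_shift_normalize(m),
         quantile = list(matrix = quantile_normalize(m), shifts = NULL))
}
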