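cluster_with_outlier <- function(seed, n = 30, gap = 10) {
  set.seed(seed)
  x <- cbind(stats::rnorm(n), stats::rnorm(n))
  out <- apply(x, 2, function(v) median(v) + gap * IQR(v))
  m <- rbind(x, out)
  rownames(m) <- c(sprintf("run%02d", seq_len(n)), "planted")
  colnames(m) <- c("f1", "f2")
  m
}

test_that("the path-length normaliser has its exact small-sample values", {
  expect_identical(iforest_cfactor(1), 0)
  expect_identical(iforest_cfactor(2), 1)          # 2*H(1) - 2*(1/2)
  expect_equal(iforest_cfactor(3), 2 * 1.5 - 4 / 3)
  expect_equal(iforest_cfactor(4), 2 * (1 + 1/2 + 1/3) - 3 / 2)
  # monotone increasing in m
  expect_true(all(diff(iforest_cfactor(2:300)) > 0))
})

test_that("fitting follows the subsample and depth rules deterministically", {
  m <- cluster_with_outlier(1, n = 19)
  fit <- fit_isolation_forest(m, seed = 42)
  expect_equal(fit$psi, 20)                        # min(256, n)
  expect_equal(fit$height_limit, ceiling(log2(20)))
  depths <- vapply(fit$trees, mscohort:::.tree_depth, integer(1))
  expect_true(all(depths <= fit$height_limit))
  fit2 <- fit_isolation_forest(m, seed = 42)
  expect_identical(fit$trees, fit2$trees)
  expect_error(fit_isolation_forest(matrix(1, 5, 3)), "constant")
})

test_that("anomaly scores are valid and match an independent tree walker", {
  m <- cluster_with_outlier(7, n = 5, gap = 3)[1:5, ]
  fit <- fit_isolation_forest(m, seed = 3)
  sc <- score_anomalies(fit, m)
  expect_true(all(sc$anomaly_score > 0 & sc$anomaly_score < 1))
  z <- sweep(sweep(m[, fit$features, drop = FALSE], 2, fit$center),
             2, fit$scale, "/")
  for (i in 1:5) {
    mpl <- mean(vapply(fit$trees, oracle_path_length, numeric(1),
                       z = z[i, ]))
    expect_equal(sc$mean_path_length[i], mpl, tolerance = 1e-12)
    expect_equal(sc$anomaly_score[i],
                 2^(-mpl / iforest_cfactor(fit$psi)), tolerance = 1e-12)
  }
})

test_that("an average point scores at or below one half", {
  set.seed(5)
  x <- cbind(stats::rnorm(40), stats::rnorm(40))
  colnames(x) <- c("f1", "f2")
  fit <- fit_isolation_forest(x, seed = 5)
  centre <- matrix(apply(x, 2, median), 1,
                   dimnames = list("centre", colnames(x)))
  sc <- score_anomalies(fit, centre)
  expect_lte(sc$anomaly_score, 0.5)
})

test_that("a distant planted point dominates the anomaly ranking", {
  top <- 0
  for (s in 1:20) {
    m <- cluster_with_outlier(s)
    fit <- fit_isolation_forest(m, seed = s)
    sc <- score_anomalies(fit, m)
    if (which.max(sc$anomaly_score) == nrow(m)) top <- top + 1
  }
  expect_gte(top, 19)
})

test_that("scores are invariant to per-feature affine rescaling", {
  m <- cluster_with_outlier(13)
  resc <- m
  resc[, 1] <- 100 * resc[, 1] - 40
  s1 <- score_anomalies(fit_isolation_forest(m, seed = 9), m)
  s2 <- score_anomalies(fit_isolation_forest(resc, seed = 9), resc)
  expect_equal(s1$anomaly_score, s2$anomaly_score, tolerance = 1e-12)
})

test_that("the outlier ranking survives run reordering", {
  m <- cluster_with_outlier(17)
  perm <- sample(nrow(m))
  s <- score_anomalies(fit_isolation_forest(m[perm, ], seed = 11),
                       m[perm, ])
  expect_equal(s$run_id[which.max(s$anomaly_score)], "planted")
})

test_that("outlier policies combine corroborated forest calls and run flags", {
  flags <- matrix(FALSE, 23, 4,
                  dimnames = list(sprintf("m%02d", 1:23),
                                  c("a", "b", "c", "d")))
  flags[1:8, "b"] <- TRUE                # run b: 8 flagged metrics
  flags[1:2, "c"] <- TRUE                # run c: 2 flagged metrics
  flags[1, "d"] <- TRUE                  # run d: 1 flagged metric
  cmx <- structure(list(flags = flags, runs = colnames(flags)),
                   class = "cohort_matrix")
  an <- data.frame(run_id = c("a", "b", "c", "d"),
                   anomaly_score = c(0.45, 0.48, 0.72, 0.70),
                   mean_path_length = 1:4,
                   is_outlier = c(FALSE, FALSE, TRUE, TRUE))
  u <- detect_outliers(an, cmx, "union")
  # b enters via >= 7 flags, c via corroborated forest call;
  # d's forest call has only one flagged metric and is suppressed
  expect_setequal(u$run_id, c("b", "c"))
  expect_equal(u$n_flagged_metrics[u$run_id == "b"], 8L)
  expect_match(u$flagged_metrics[u$run_id == "b"], "m01")
  expect_equal(u$run_id[1], "c")         # ordered by score
  i <- detect_outliers(an, cmx, "intersection")
  expect_equal(nrow(i), 0)
  # a clean cohort yields an empty report
  an0 <- transform(an, is_outlier = FALSE)
  cmx0 <- cmx; cmx0$flags[] <- FALSE
  expect_equal(nrow(detect_outliers(an0, cmx0)), 0)
})
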