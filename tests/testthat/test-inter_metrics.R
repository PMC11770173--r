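panel <- contaminant_panel("erythrocyte", c("HBB", "HBA1"))

test_that("contaminant fractions follow intensity arithmetic", {
  clean <- toy_report(3, protein_group = c("P1", "P2", "P3"),
                      protein_intensity = c(100, 200, 300))
  expect_equal(contaminant_fraction(clean, panel), 0)

  all_in <- toy_report(2, protein_group = c("HBB", "HBA1"),
                       protein_intensity = c(10, 90))
  expect_equal(contaminant_fraction(all_in, panel), 1)

  mixed <- toy_report(2, protein_group = c("HBB;P9", "P2"),
                      protein_intensity = c(300, 700))
  expect_equal(contaminant_fraction(mixed, panel), 0.30)

  none <- toy_report(2, protein_intensity = c(NA, NA))
  expect_true(is.na(contaminant_fraction(none, panel)))
})

test_that("pairwise RT MSE obeys closed forms and symmetry", {
  a <- toy_report(100, run_id = "a", apex_rt = seq(1, 20, length.out = 100))
  b <- toy_report(100, run_id = "b", apex_rt = seq(1, 20, length.out = 100))
  r0 <- rt_deviation_metrics(list(a, b), min_shared = 50)
  expect_equal(r0$rt_mse["a", "b"], 0)
  expect_equal(diag(r0$rt_mse), c(a = 0, b = 0))

  shift <- toy_report(100, run_id = "s",
                      apex_rt = seq(1, 20, length.out = 100) + 0.5)
  r1 <- rt_deviation_metrics(list(a, shift), min_shared = 50)
  expect_equal(r1$rt_mse["a", "s"], 0.25)
  expect_equal(r1$mean_rt_mse[["a"]], 0.25)

  set.seed(11)
  coh <- generate_cohort(cohort_config(n_runs = 4, n_proteins = 60, seed = 11),
                         with_scans = FALSE)
  rr <- rt_deviation_metrics(coh$reports)
  expect_equal(rr$rt_mse, t(rr$rt_mse))
  expect_true(all(rr$rt_mse >= 0, na.rm = TRUE))
})

test_that("pairs sharing too few precursors are non-computable", {
  a <- toy_report(10, run_id = "a")
  b <- toy_report(10, run_id = "b")
  r <- rt_deviation_metrics(list(a, b), min_shared = 50)
  expect_true(is.na(r$rt_mse["a", "b"]))
})

test_that("distribution statistics match quantile and MAD oracles", {
  # log2 intensities {1..5}: median 3, IQR 2 under linear-interpolation quantiles
  a <- toy_report(5, run_id = "a", precursor_intensity = 2^(1:5))
  b <- toy_report(5, run_id = "b", precursor_intensity = 2^(1:5))
  q <- quant_distribution_metrics(list(a, b), "precursor", min_shared = 3)
  expect_equal(q$median_log2_intensity, c(3, 3))
  expect_equal(q$iqr_log2_intensity, c(2, 2))
  expect_equal(q$median_pearson, c(1, 1))
  expect_equal(q$norm_factor, c(0, 0))
  expect_equal(q$n_ids, c(5, 5))

  # MAD-zero vector
  c4 <- toy_report(4, run_id = "c", precursor_intensity = 2^c(1, 1, 1, 9))
  q2 <- quant_distribution_metrics(list(c4, c4), "precursor", min_shared = 3)
  expect_equal(q2$robust_sd_log2_intensity, c(0, 0))
})

test_that("robust SD agrees with the stats::mad oracle", {
  set.seed(3)
  for (i in 1:200) {
    x <- stats::rnorm(sample(5:60, 1), sd = exp(stats::runif(1, -2, 2)))
    expect_equal(robust_sd(x), stats::mad(x), tolerance = 1e-12)
  }
})

test_that("the cohort matrix carries exactly the 23 catalogued metrics", {
  cat23 <- inter_metric_catalogue()
  expect_equal(nrow(cat23), 23)
  expect_equal(sum(startsWith(cat23$metric_id, "sp_")), 3)
  expect_equal(sum(startsWith(cat23$metric_id, "lc_")), 2)

  coh <- generate_cohort(cohort_config(n_runs = 6, n_proteins = 60, seed = 5),
                         with_scans = FALSE)
  cm <- build_cohort_matrix(coh$reports)
  expect_equal(rownames(cm$values), cat23$metric_id)
  expect_equal(ncol(cm$values), 6)
  expect_true(all(cm$scores >= 1 & cm$scores <= 5, na.rm = TRUE))
  expect_true(all(cm$values[1:3, ] >= 0 & cm$values[1:3, ] <= 1))
  # pairwise matrices: symmetric, fixed diagonals
  expect_equal(cm$pairwise$rt_mse, t(cm$pairwise$rt_mse))
  expect_equal(unname(diag(cm$pairwise$rt_mse)), rep(0, 6))
  expect_equal(unname(diag(cm$pairwise$pearson_log2_protein)), rep(1, 6))
})

test_that("a grossly contaminated run is flagged on the SP metrics", {
  cfg <- cohort_config(n_runs = 10, n_proteins = 60, seed = 9,
                       anomalies = list(list(run = 4, type = "contamination",
                                             magnitude = 0.3)))
  coh <- generate_cohort(cfg, with_scans = FALSE)
  cm <- build_cohort_matrix(coh$reports)
  expect_true(any(cm$flags[c("sp_erythrocyte", "sp_cellular_debris",
                             "sp_serum_high_abundance"), "run04"]))
  expect_true(all(!cm$flags["sp_erythrocyte", colnames(cm$flags) != "run04"]))
})

test_that("the 2-SD scoring is affine-invariant and direction-aware", {
  set.seed(21)
  x <- stats::rnorm(20)
  for (dir in c("bad_high", "bad_low", "bad_both")) {
    base <- score_inter_metric(x, dir)
    resc <- score_inter_metric(3.2 * x + 7, dir)
    expect_equal(base$flag, resc$flag)
    expect_equal(base$score, resc$score, tolerance = 1e-9)
  }
  # direction: only the bad side scores below 5
  v <- c(rep(0, 10), 5)
  hi <- score_inter_metric(v, "bad_high")
  expect_lt(hi$score[11], 5)
  expect_true(all(hi$score[1:10] == 5))
  lo <- score_inter_metric(v, "bad_low")
  expect_equal(lo$score[11], 5)
})

test_that("constant metrics neither score down nor flag", {
  r <- score_inter_metric(rep(4, 8), "bad_high")
  expect_true(all(r$score == 5))
  expect_true(all(!r$flag))
})

test_that("run-level flagging applies the >= k flagged-metrics rule", {
  fake <- function(nflag) {
    flags <- matrix(FALSE, 23, 3,
                    dimnames = list(sprintf("m%02d", 1:23),
                                    c("r1", "r2", "r3")))
    flags[seq_len(nflag), "r2"] <- TRUE
    structure(list(flags = flags, runs = colnames(flags)),
              class = "cohort_matrix")
  }
  expect_equal(flag_low_quality(fake(7)), "r2", ignore_attr = TRUE)
  expect_length(flag_low_quality(fake(6)), 0)
  expect_length(flag_low_quality(fake(0)), 0)
})

test_that("clean cohorts produce no run-level low-quality calls", {
  hits <- 0
  for (s in 1:10) {
    coh <- generate_cohort(cohort_config(n_runs = 12, n_proteins = 50,
                                         seed = 600 + s),
                           with_scans = FALSE)
    cm <- build_cohort_matrix(coh$reports)
    hits <- hits + length(flag_low_quality(cm))
  }
  expect_equal(hits, 0)
})

test_that("two-run cohorts report values but suppress scores", {
  coh <- generate_cohort(cohort_config(n_runs = 2, n_proteins = 40, seed = 2),
                         with_scans = FALSE)
  expect_warning(cm <- build_cohort_matrix(coh$reports), "fewer than 3")
  expect_true(all(is.na(cm$scores)))
  expect_false(all(is.na(cm$values)))
})
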