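test_that("DIA decomposition recovers constructed counts and the identity", {
  # 1000 acquired, 800 identified, 1600 redundant, 1000 unique
  fx <- dia_run_from_counts(20, 800, 1600, 1000, n_cycles = 50)
  d <- decompose_dia_score(fx$report, fx$scans)
  expect_equal(d$n_acquired_ms2, 1000)
  expect_equal(d$n_identified_ms2, 800)
  expect_equal(d$n_redundant_precursors, 1600)
  expect_equal(d$n_unique_precursors, 1000)
  expect_equal(d$q_ms2, 0.8)
  expect_equal(d$spectra_complexity, 2.0)
  expect_equal(d$dup_rate, 1.6)
  expect_equal(d$utilization, 1.25)
  expect_equal(d$n_acquired_ms2 * d$q_ms2 * d$utilization,
               d$n_unique_precursors)
})

test_that("one precursor per identified MS2 scan gives unit ratios", {
  fx <- dia_run_from_counts(4, 30, 30, 30)
  d <- decompose_dia_score(fx$report, fx$scans)
  expect_equal(d$spectra_complexity, 1)
  expect_equal(d$dup_rate, 1)
  expect_equal(d$utilization, 1)
  expect_equal(d$n_unique_precursors, d$n_identified_ms2)
})

test_that("decomposition is invariant to report row order", {
  fx <- dia_run_from_counts(6, 60, 130, 80)
  d1 <- decompose_dia_score(fx$report, fx$scans)
  rec <- fx$report$records
  set.seed(1)
  shuf <- ident_report(fx$report$run_id, rec[sample(nrow(rec)), ],
                       fx$report$gradient_length)
  d2 <- decompose_dia_score(shuf, fx$scans)
  expect_equal(unclass(d1), unclass(d2))
})

test_that("DDA decomposition follows its factorisation", {
  scans <- toy_scans(n_cycles = 100, n_windows = 5)   # 500 MS2
  k <- c(rep(2, 20), rep(1, 360))                     # 400 identified scans
  rep380 <- toy_report(380, n_ms2_matched = k)
  d <- decompose_dda_score(rep380, scans)
  expect_equal(d$q_ms2, 0.8)
  expect_equal(d$p_ms2_per_precursor, 0.95)
  expect_equal(d$n_acquired_ms2 * d$q_ms2 * d$p_ms2_per_precursor,
               d$n_unique_precursors)

  all_unique <- toy_report(500, n_ms2_matched = 1)
  d2 <- decompose_dda_score(all_unique, scans)
  expect_equal(d2$q_ms2, 1)
  expect_equal(d2$p_ms2_per_precursor, 1)

  none <- toy_report(3, n_ms2_matched = 0)
  d3 <- decompose_dda_score(none, scans)
  expect_false(d3$computable)
  expect_true(is.na(d3$p_ms2_per_precursor))
})

test_that("scan metrics report cycle time, TIC stability and fill levels", {
  flat <- toy_scans(n_cycles = 100, n_windows = 2, cycle_s = 1.2)
  m <- compute_scan_metrics(flat)
  g <- function(id) m$value[m$metric_id == id]
  expect_equal(g("median_cycle_time"), 1.2, tolerance = 1e-9)
  expect_equal(g("tic_cv"), 0)
  expect_equal(g("tic_jump_count"), 0)
  expect_equal(g("n_ms1_scans"), 100)
  expect_equal(g("n_ms2_scans"), 200)

  tic <- rep(1e9, 100); tic[50] <- 1e11
  spiky <- toy_scans(n_cycles = 100, n_windows = 2, tic1 = tic)
  ms <- compute_scan_metrics(spiky)
  expect_equal(ms$value[ms$metric_id == "tic_jump_count"], 2)
})

test_that("cycle-time metrics need at least two cycles", {
  one <- toy_scans(n_cycles = 1, n_windows = 3)
  m <- compute_scan_metrics(one)
  row <- m[m$metric_id == "median_cycle_time", ]
  expect_false(row$computable)
  expect_match(row$reason, "cycles")
})

test_that("identification metrics match hand-computed values", {
  rep4 <- toy_report(4, missed_cleavages = c(0, 1, 0, 0))
  m <- compute_ident_metrics(rep4)
  g <- function(id) m$value[m$metric_id == id]
  expect_equal(g("missed_cleavage_rate"), 25)
  expect_equal(g("median_ms1_mass_accuracy"), 0)
  expect_equal(g("n_precursors"), 4)
  expect_equal(g("n_peptides"), 4)

  # 101 sorted protein intensities with x[2] = 1e3 and x[100] = 1e7, so the
  # interpolated 1st/99th percentiles are exactly 1e3 and 1e7
  v <- sort(c(500, 10^seq(3, 7, length.out = 99), 2e7))
  rep101 <- toy_report(101, protein_intensity = v)
  m2 <- compute_ident_metrics(rep101)
  expect_equal(m2$value[m2$metric_id == "intensity_dynamic_range"], 4,
               tolerance = 1e-9)
})

test_that("mass accuracy reflects planted ppm deviations", {
  rep3 <- toy_report(3, theoretical_mz = c(500, 600, 700),
                     measured_mz = c(500, 600, 700) * (1 + 2e-6))
  m <- compute_ident_metrics(rep3)
  expect_equal(m$value[m$metric_id == "median_ms1_mass_accuracy"], 2,
               tolerance = 1e-6)
})

test_that("sequence coverage requires a database and uses it when given", {
  rep1 <- toy_report(1, stripped_sequence = "ACDEF", protein_group = "P1")
  m0 <- compute_ident_metrics(rep1)
  expect_false(m0$computable[m0$metric_id == "mean_protein_sequence_coverage"])
  db <- c(P1 = "ACDEFGHIKL")   # 5 of 10 residues covered
  m1 <- compute_ident_metrics(rep1, protein_db = db)
  expect_equal(m1$value[m1$metric_id == "mean_protein_sequence_coverage"], 50)
})

test_that("LC delay and tail follow the cumulative-identification quantiles", {
  set.seed(7)
  rt <- seq(2, 28, length.out = 400)
  rep400 <- toy_report(400, apex_rt = rt)
  m <- compute_chromatography_metrics(rep400)
  g <- function(id) m$value[m$metric_id == id]
  expect_lt(abs(g("lc_delay_time") - 2), 1)
  expect_lt(abs(g("lc_tail_time") - 2), 1)
  expect_equal(g("active_gradient_fraction"), 26 / 30, tolerance = 0.05)
  h <- attr(m, "rt_histogram")
  expect_equal(sum(h$n_identifications), 400)

  late <- toy_report(50, apex_rt = seq(12, 29, length.out = 50))
  m2 <- compute_chromatography_metrics(late)
  expect_gte(m2$value[m2$metric_id == "lc_delay_time"], 12)

  empty <- ident_report("e", toy_records(0))
  m3 <- compute_chromatography_metrics(empty)
  expect_true(all(!m3$computable))
  expect_true(all(nzchar(m3$reason)))
})

test_that("window metrics report geometry and precursor load", {
  sc <- toy_scans(n_cycles = 3, n_windows = 22, mz_lo = 350,
                  width = (1200 - 350) / 22)
  rep1 <- toy_report(1, measured_mz = 355)
  m <- compute_window_metrics(sc, rep1)
  g <- function(id) m$value[m$metric_id == id]
  expect_equal(g("n_windows_per_cycle"), 22)
  expect_equal(g("mean_window_width"), (1200 - 350) / 22, tolerance = 1e-9)
  pw <- attr(m, "per_window_counts")
  expect_equal(pw$n_precursors[1], 1)   # 355 Th sits in the first window
  expect_equal(sum(pw$n_precursors), 1)

  # uniform load over 80 equal windows is balanced
  sc80 <- toy_scans(n_cycles = 2, n_windows = 80, mz_lo = 400, width = 6)
  mz <- 400 + 6 * (rep(seq_len(80), each = 3) - 1) + c(1, 3, 5)
  rep240 <- toy_report(240, measured_mz = mz)
  m80 <- compute_window_metrics(sc80, rep240)
  expect_equal(m80$value[m80$metric_id == "window_load_imbalance"], 1)
})

test_that("feature detection links traces and matches identifications", {
  sc <- toy_scans(n_cycles = 6, n_windows = 2)
  m1_idx <- sc$scans$scan_index[sc$scans$ms_level == 1]
  gauss <- dnorm(1:5, 3, 1) * 1e7
  cen <- data.frame(scan_index = m1_idx[1:5], mz = 500.000,
                    intensity = gauss)
  sc$centroids <- cen
  rep1 <- toy_report(1, measured_mz = 500.000,
                     apex_rt = sc$scans$rt[sc$scans$scan_index == m1_idx[3]])
  res <- detect_ms1_features(sc, rep1)
  expect_equal(nrow(res$features), 1)
  expect_equal(res$features$n_scans, 5)
  expect_equal(res$identified_feature_fraction, 1.0)

  # two traces 50 ppm apart stay separate at 10 ppm tolerance
  cen2 <- rbind(cen, transform(cen, mz = 500 * (1 + 50e-6)))
  sc$centroids <- cen2
  res2 <- detect_ms1_features(sc, rep1, ppm_tol = 10)
  expect_equal(nrow(res2$features), 2)
  expect_equal(res2$identified_feature_fraction, 0.5)

  sc$centroids <- NULL
  expect_error(detect_ms1_features(sc, rep1), "not computable")
})

test_that("fraction and percent metrics stay within bounds", {
  for (s in 1:5) {
    fx <- random_counts_run(s + 400)
    m <- rbind(compute_scan_metrics(fx$scans),
               compute_ident_metrics(fx$report))
    pct <- m[m$unit %in% c("%", "fraction") & m$computable, ]
    lim <- ifelse(pct$unit == "%", 100, 1)
    expect_true(all(pct$value >= 0 & pct$value <= lim))
  }
})
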