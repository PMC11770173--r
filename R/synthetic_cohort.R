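#' Configure a synthetic cohort
#'
#' Defines the study conditions emulated by the generator: a shared latent
#' precursor catalogue with log-normal intensities and common retention
#' times plus per-run jitter, a DIA cycle structure, and optional planted
#' anomalies with known ground truth.
#'
#' @param n_runs Number of runs (default 20, a typical QC batch).
#' @param n_proteins Catalogue proteins (default 150).
#' @param peptides_per_protein Mean peptides per protein (default 4).
#' @param gradient_length Gradient length, minutes (default 30).
#' @param n_windows DIA isolation windows per cycle (default 20).
#' @param mz_range Precursor m/z range covered by the windows (Th).
#' @param log2_intensity Mean and SD of catalogue log2 intensity.
#' @param rt_jitter_sd Per-run retention-time jitter SD, minutes.
#' @param q_ms2_target Baseline per-run detection probability of a
#'   catalogue precursor (default 0.85).
#' @param anomalies List of `list(run =, type =, magnitude =)` entries with
#'   type one of `"contamination"` (target contaminant intensity fraction),
#'   `"rt_drift"` (constant shift, minutes), `"intensity_drop"`
#'   (attenuation factor, intensities divided by it), `"low_id_rate"`
#'   (identification-retention probability).
#' @param seed Integer seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_runs = 20, n_proteins = 150,
                          peptides_per_protein = 4, gradient_length = 30,
                          n_windows = 20, mz_range = c(400, 1000),
                          log2_intensity = c(mean = 20, sd = 2),
                          rt_jitter_sd = 0.05, q_ms2_target = 0.85,
                          anomalies = list(), seed = 1) {
  stopifnot(n_runs >= 1, n_proteins >= 1, peptides_per_protein >= 1,
            gradient_length > 0, n_windows >= 1,
            length(mz_range) == 2, mz_range[1] < mz_range[2],
            q_ms2_target > 0, q_ms2_target <= 1)
  for (a in anomalies) {
    stopifnot(a$run >= 1, a$run <= n_runs,
              a$type %in% c("contamination", "rt_drift", "intensity_drop",
                            "low_id_rate"))
    if (a$type %in% c("contamination", "low_id_rate"))
      stopifnot(a$magnitude > 0, a$magnitude <= 1)
  }
  structure(list(n_runs = n_runs, n_proteins = n_proteins,
                 peptides_per_protein = peptides_per_protein,
                 gradient_length = gradient_length, n_windows = n_windows,
                 mz_range = mz_range, log2_intensity = log2_intensity,
                 rt_jitter_sd = rt_jitter_sd, q_ms2_target = q_ms2_target,
                 anomalies = anomalies, seed = seed),
            class = "cohort_config")
}

.random_peptide <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1L]]
  vapply(seq_len(n), function(i) {
    len <- sample(7:18, 1)
    paste0(paste(sample(aa, len, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate a reproducible synthetic cohort
#'
#' Draws a latent catalogue once, then emits per-run identification reports
#' (and, optionally, consistent DIA scan tables) with run-level noise and
#' the configured planted anomalies.  A fixed seed yields byte-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @param with_scans Generate scan tables too (default TRUE).  Inter-run
#'   analyses only need the reports; skipping scan tables makes large
#'   simulation sweeps much cheaper.
#' @return List with `reports` (list of `ident_report`), `scans` (list of
#'   `scan_table` or NULL), `ground_truth` (data frame `run_id,
#'   anomaly_type, magnitude`) and `config`.
#' @export
generate_cohort <- function(config, with_scans = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  wwidth <- diff(config$mz_range) / config$n_windows
  if (wwidth <= 1)
    stop("infeasible window/mz combination: window width ", round(wwidth, 2),
         " Th")
  set.seed(config$seed)
  g <- config$gradient_length
  cyc_min <- 2 / 60                       # 2-s duty cycle
  # --- latent catalogue ---------------------------------------------------
  n_pep <- pmax(1, stats::rpois(config$n_proteins,
                                config$peptides_per_protein - 1) + 1)
  prot_of_pep <- rep(seq_len(config$n_proteins), n_pep)
  npep <- length(prot_of_pep)
  pep_seq <- .random_peptide(npep)
  pep_mc <- stats::rbinom(npep, 1, 0.12)
  extra <- stats::runif(npep) < 0.15      # second charge state
  pep_of_prec <- c(seq_len(npep), which(extra))
  charge <- c(rep(2L, npep), rep(3L, sum(extra)))
  nprec <- length(pep_of_prec)
  mz <- stats::runif(nprec, config$mz_range[1] + 0.5,
                     config$mz_range[2] - 0.5)
  rt <- stats::runif(nprec, 0.07 * g, 0.93 * g)
  base_l2 <- stats::rnorm(nprec, config$log2_intensity[["mean"]],
                          config$log2_intensity[["sd"]])
  prec_id <- sprintf("%s%s.%d", pep_seq[pep_of_prec],
                     ifelse(charge == 3, "+", ""), charge)
  prot_name <- sprintf("PROT%04d", prot_of_pep[pep_of_prec])
  anom <- config$anomalies
  anom_of <- rep("none", config$n_runs)
  mag_of <- rep(NA_real_, config$n_runs)
  for (a in anom) { anom_of[a$run] <- a$type; mag_of[a$run] <- a$magnitude }
  contam_members <- c("HBB", "HBA1", "HBD", "CA1", "SPTA1",
                      "KRT1", "KRT10", "ACTB", "GAPDH",
                      "ALB", "TF", "HP")
  reports <- vector("list", config$n_runs)
  scans <- if (with_scans) vector("list", config$n_runs) else NULL
  run_ids <- sprintf("run%02d", seq_len(config$n_runs))
  for (r in seq_len(config$n_runs)) {
    rid <- run_ids[r]
    det <- stats::runif(nprec) < config$q_ms2_target
    run_shift <- stats::rnorm(1, 0, 0.1)
    l2 <- base_l2 + run_shift + stats::rnorm(nprec, 0, 0.3)
    apex <- pmin(pmax(rt + stats::rnorm(nprec, 0, config$rt_jitter_sd), 0), g)
    drt <- apex - rt
    fwhm <- exp(stats::rnorm(nprec, log(0.22), 0.2))
    pw <- fwhm * 2
    rec <- data.frame(
      run_id = rid,
      precursor_id = prec_id,
      stripped_sequence = pep_seq[pep_of_prec],
      charge = charge,
      measured_mz = mz * (1 + stats::rnorm(nprec, 0, 0.3e-6)),
      theoretical_mz = mz,
      apex_rt = apex, delta_rt = drt, fwhm = fwhm, peak_width = pw,
      missed_cleavages = pep_mc[pep_of_prec],
      precursor_intensity = 2^l2,
      peptide_intensity = NA_real_,
      protein_group = prot_name,
      protein_intensity = NA_real_,
      q_value = stats::runif(nprec, 0, 0.01),
      n_ms2_matched = pmax(1, pmin(round(pw / cyc_min), 12)),
      stringsAsFactors = FALSE)[det, , drop = FALSE]
    # planted anomalies ----------------------------------------------------
    ty <- anom_of[r]; mg <- mag_of[r]
    if (ty == "rt_drift") {
      rec$apex_rt <- pmin(rec$apex_rt + mg, g)
      rec$delta_rt <- rec$delta_rt + mg
    } else if (ty == "intensity_drop") {
      rec$precursor_intensity <- rec$precursor_intensity / mg
    } else if (ty == "low_id_rate") {
      rec <- rec[stats::runif(nrow(rec)) < mg, , drop = FALSE]
    }
    # rollup intensities ---------------------------------------------------
    pint <- tapply(rec$precursor_intensity, rec$stripped_sequence, sum)
    rec$peptide_intensity <- as.numeric(pint[rec$stripped_sequence])
    prot <- tapply(rec$precursor_intensity, rec$protein_group, sum)
    rec$protein_intensity <- as.numeric(prot[rec$protein_group])
    if (ty == "contamination") {
      clean_total <- sum(prot)
      target <- clean_total * mg / (1 - mg)
      nc <- length(contam_members)
      w <- stats::rlnorm(nc, 0, 1)
      cint <- target * w / sum(w)
      crt <- stats::runif(nc, 0.1 * g, 0.9 * g)
      cmz <- stats::runif(nc, config$mz_range[1] + 0.5,
                          config$mz_range[2] - 0.5)
      cfw <- exp(stats::rnorm(nc, log(0.22), 0.2))
      crec <- data.frame(
        run_id = rid,
        precursor_id = paste0("CONT_", contam_members, ".2"),
        stripped_sequence = paste0("CONTPEP", seq_len(nc), "K"),
        charge = 2L,
        measured_mz = cmz, theoretical_mz = cmz,
        apex_rt = crt, delta_rt = stats::rnorm(nc, 0, 0.02),
        fwhm = cfw, peak_width = cfw * 2,
        missed_cleavages = 0,
        precursor_intensity = cint, peptide_intensity = cint,
        protein_group = contam_members, protein_intensity = cint,
        q_value = stats::runif(nc, 0, 0.01),
        n_ms2_matched = pmax(1, pmin(round(cfw * 2 / cyc_min), 12)),
        stringsAsFactors = FALSE)
      rec <- rbind(rec, crec)
    }
    rownames(rec) <- NULL
    reports[[r]] <- ident_report(rid, rec, gradient_length = g)
    if (with_scans)
      scans[[r]] <- .synthetic_scan_table(rid, config, cyc_min)
  }
  list(reports = reports, scans = scans,
       ground_truth = data.frame(run_id = run_ids, anomaly_type = anom_of,
                                 magnitude = mag_of,
                                 stringsAsFactors = FALSE),
       config = config)
}

.synthetic_scan_table <- function(rid, config, cyc_min) {
  g <- config$gradient_length
  W <- config$n_windows
  ncyc <- floor(g / cyc_min)
  wwidth <- diff(config$mz_range) / W
  lo <- config$mz_range[1] + (seq_len(W) - 1) * wwidth
  cyc <- rep(seq_len(ncyc), each = W + 1)
  lev <- rep(c(1L, rep(2L, W)), ncyc)
  t0 <- (cyc - 1) * cyc_min
  off <- rep(c(0, seq_len(W) * cyc_min / (W + 1)), ncyc)
  rtmin <- t0 + off
  # bell-shaped TIC over the gradient with mild log-normal noise
  hump <- exp(-((t0 - g / 2) / (g / 3))^2)
  tic1 <- 1e9 * (0.2 + hump) * stats::rlnorm(length(cyc), 0, 0.05)
  tic <- ifelse(lev == 1, tic1, tic1 / 20)
  df <- data.frame(
    scan_index = seq_along(cyc), ms_level = lev, rt = rtmin, tic = tic,
    base_peak_intensity = tic / 10,
    peak_count = ifelse(lev == 1, stats::rpois(length(cyc), 1200),
                        stats::rpois(length(cyc), 150)),
    injection_time = ifelse(lev == 1,
                            pmax(stats::rnorm(length(cyc), 20, 2), 1),
                            pmax(stats::rnorm(length(cyc), 28, 3), 1)),
    iso_lo = ifelse(lev == 1, NA_real_, rep(c(NA, lo), ncyc)),
    iso_hi = ifelse(lev == 1, NA_real_, rep(c(NA, lo + wwidth), ncyc)))
  scan_table(rid, df)
}

#' Write a generated cohort to disk
#'
#' Emits one identification-report TSV (canonical headers) and optionally
#' one scan-table TSV per run, plus the ground-truth table.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rep in cohort$reports)
    utils::write.table(rep$records,
                       file.path(dir, paste0(rep$run_id, "_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$scans))
    for (sc in cohort$scans)
      utils::write.table(sc$scans[, c("scan_index", "ms_level", "rt", "tic",
                                      "base_peak_intensity", "peak_count",
                                      "injection_time", "iso_lo", "iso_hi")],
                         file.path(dir, paste0(sc$run_id, "_scans.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Construct a minimal DIA run realising given decomposition counts
#'
#' Builds a consistent scan-table / identification-report pair whose
#' [decompose_dia_score()] reproduces exactly the requested counts of
#' identified MS2 scans, redundant precursor identifications and unique
#' precursors.  Precursors are laid out over isolation windows and
#' consecutive cycles so that the window/RT scan assignment recovers the
#' construction.  Deterministic (no randomness).
#'
#' @param n_windows Isolation windows per cycle.
#' @param n_identified_ms2 MS2 scans that identify at least one precursor.
#' @param n_redundant Total precursor-scan identifications.
#' @param n_unique Unique precursors.
#' @param window_width Window width, Th (default 6).
#' @param mz_lo Lower m/z bound of the first window (default 400).
#' @param run_id Run identifier.
#' @param n_cycles Acquisition cycles; default just enough to hold the
#'   identified scans plus two blank cycles.  The acquired-MS2 count is
#'   `n_cycles * n_windows`.
#' @return List with `report` and `scans`.
#' @export
dia_run_from_counts <- function(n_windows, n_identified_ms2, n_redundant,
                                n_unique, window_width = 6, mz_lo = 400,
                                run_id = "fixture", n_cycles = NULL) {
  W <- n_windows; I <- n_identified_ms2; R <- n_redundant; U <- n_unique
  stopifnot(R >= U, R >= I, U >= 1, I >= 1)
  k <- rep(R %/% U, U)
  rem <- R - sum(k)
  if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
  A <- min(W, U, I %/% max(k))
  if (A < 1)
    stop("infeasible counts: duplicate rate too high for the identified-scan budget")
  m <- rep(I %/% A, A)
  remi <- I - sum(m)
  if (remi > 0) m[seq_len(remi)] <- m[seq_len(remi)] + 1
  # deal precursors (largest k first) round-robin over active windows
  ord <- order(-k)
  win_of <- integer(U)
  win_of[ord] <- rep(seq_len(A), length.out = U)
  # ensure every window's identification budget is coverable
  for (w in seq_len(A))
    if (sum(k[win_of == w]) < m[w])
      stop("internal: window ", w, " cannot cover its cycles")
  cyc_min <- 1 / 60
  start <- integer(U); endc <- integer(U)
  for (w in seq_len(A)) {
    js <- which(win_of == w)
    pos <- 1L
    covered <- rep(FALSE, m[w])
    for (j in js) {
      st <- max(1L, min(pos, m[w] - k[j] + 1L))
      start[j] <- st; endc[j] <- st + k[j] - 1L
      covered[st:endc[j]] <- TRUE
      pos <- st + k[j]
      if (pos > m[w]) pos <- 1L
    }
    if (!all(covered))
      stop("internal: coverage gap in window ", w)
  }
  C <- if (is.null(n_cycles)) max(m) + 2L else as.integer(n_cycles)
  stopifnot(C >= max(m))
  # scan table: each cycle = MS1 + W MS2 scans, 1-s cycles
  lo <- mz_lo + (seq_len(W) - 1) * window_width
  cyc <- rep(seq_len(C), each = W + 1)
  lev <- rep(c(1L, rep(2L, W)), C)
  rtv <- (cyc - 1) * cyc_min + rep(c(0, seq_len(W) * cyc_min / (W + 1)), C)
  sdf <- data.frame(
    scan_index = seq_along(cyc), ms_level = lev, rt = rtv,
    tic = ifelse(lev == 1, 1e9, 5e7),
    base_peak_intensity = ifelse(lev == 1, 1e8, 5e6),
    peak_count = ifelse(lev == 1, 1000L, 150L),
    injection_time = ifelse(lev == 1, 20, 30),
    iso_lo = ifelse(lev == 1, NA_real_, rep(c(NA, lo), C)),
    iso_hi = ifelse(lev == 1, NA_real_, rep(c(NA, lo + window_width), C)))
  scans <- scan_table(run_id, sdf)
  # report rows
  w_j <- win_of
  idx_in_win <- stats::ave(seq_len(U), w_j, FUN = seq_along)
  n_in_win <- stats::ave(seq_len(U), w_j, FUN = length)
  mzv <- mz_lo + (w_j - 1) * window_width +
    window_width * idx_in_win / (n_in_win + 1)
  apex <- ((start + endc) / 2 - 1) * cyc_min + w_j * cyc_min / (W + 1)
  pwv <- (endc - start + 1.5) * cyc_min
  rec <- data.frame(
    run_id = run_id,
    precursor_id = sprintf("SEQ%05dK.2", seq_len(U)),
    stripped_sequence = sprintf("SEQ%05dK", seq_len(U)),
    charge = 2L,
    measured_mz = mzv, theoretical_mz = mzv,
    apex_rt = apex, delta_rt = 0, fwhm = pwv / 2, peak_width = pwv,
    missed_cleavages = 0,
    precursor_intensity = 2^(18 + (seq_len(U) %% 40) / 10),
    peptide_intensity = 2^(18 + (seq_len(U) %% 40) / 10),
    protein_group = sprintf("P%04d", (seq_len(U) - 1) %/% 3 + 1),
    protein_intensity = 3 * 2^(18 + (seq_len(U) %% 40) / 10),
    q_value = 0.001,
    n_ms2_matched = k,
    stringsAsFactors = FALSE)
  report <- ident_report(run_id, rec, gradient_length = C * cyc_min)
  list(report = report, scans = scans)
}

#' Worked-example DIA fixtures
#'
#' Two deterministic fixtures reproducing the canonical 80-window and
#' 22-window DIA decompositions: with 80 windows per cycle the spectra
#' complexity is 2.27 and the duplicate-identification rate 1.58, giving an
#' MS2 utilization rate of 1.44; with 22 windows the complexity rises to
#' 4.1 but the duplicate rate to 4.07, leaving a utilization of only 1.01.
#'
#' @param which `"win80"` or `"win22"`.
#' @return List with `report` and `scans`.
#' @examples
#' d <- decompose_dia_score(worked_example_fixture("win22")$report,
#'                          worked_example_fixture("win22")$scans)
#' round(d$utilization, 2)   # 1.01
#' @export
worked_example_fixture <- function(which = c("win80", "win22")) {
  which <- match.arg(which)
  if (which == "win80")
    dia_run_from_counts(80, 100, 227, 144, window_width = 6,
                        run_id = "win80_example")
  else
    dia_run_from_counts(22, 1000, 4111, 1010, window_width = 26,
                        run_id = "win22_example")
}
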