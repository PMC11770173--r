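---
title: "Methods: how mscohort measures, scores and flags LC-MS runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mscohort measures, scores and flags LC-MS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscohort)
```

This vignette documents the models and procedures implemented in `mscohort`,
the assumptions behind them, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-cohort tests do and do not
demonstrate about real data.

## 1. The per-run scoring decomposition

For a DIA run, four counts are taken from the identification report and the
scan table: acquired MS2 scans $N_{a}$, identified MS2 scans $N_{i}$ (scans
that yielded at least one precursor identification), redundant precursor
identifications $N_{r}$ (the sum over precursors of the number of scans each
was identified in), and unique precursors $N_{u}$.  Everything else is a
ratio of these:

$$N_u \;=\; N_a \times \underbrace{\frac{N_i}{N_a}}_{Q_{MS2}} \times
\Big(\underbrace{\tfrac{N_r}{N_i}}_{\text{complexity}} \big/
\underbrace{\tfrac{N_r}{N_u}}_{\text{duplicate rate}}\Big)$$

The identity is algebraic — it holds to machine precision whenever the four
counts come from one consistent assignment of precursors to scans — and the
tests verify it to a relative $10^{-9}$ on 1000 randomly constructed runs.
Its value is diagnostic, not inferential: each factor isolates one failure
mode (acquisition speed, scan identifiability, window sizing).

**Reconstructing $N_i$.**  Report dialects carry a per-precursor
identified-scan count (`n_ms2_matched`) but not the scan identities, so the
set of identified scans is reconstructed: each precursor is mapped to the MS2
scans whose isolation window contains its measured m/z and whose retention
time lies within half a peak width of the apex, truncated to the
`n_ms2_matched` scans nearest the apex (ties broken by scan index).  Without
`n_ms2_matched` all window/RT-compatible scans are used.  This assumes the
isolation scheme is constant across cycles (violations are warned about at
read time) and that elution is contiguous.  For DDA, where a scan identifies
at most one precursor, $N_i = \sum$ `n_ms2_matched` and no reconstruction is
needed.

## 2. Metric extraction

Scan-level metrics (cycle time, injection times, peak counts, base-peak
intensities, TIC stability) are medians over the run; identification-level
metrics cover counts at the three rollup levels, missed cleavages, peak
shape, mass accuracy and intensity spread.  Choices worth noting:

* **LC delay / tail time** use the 0.5 % / 99.5 % quantiles of the apex-RT
  distribution (`edge_quantile = 0.005`): the time before the first
  identifiable analytes elute is then robust to a single stray early
  identification, unlike the literal first apex.
* **Ion-source instability** is counted as adjacent MS1 TIC ratios beyond
  10-fold (`jump_ratio = 10`), two counts per isolated spike (up and down).
  The category is standard; the specific statistic is this package's
  definition.
* **Mass accuracy** is the median of $|m/z_{meas} - m/z_{theo}|/m/z_{theo}
  \times 10^6$ (ppm); charge handling is the report producer's concern.
* **MS1 feature detection** is deliberately simple trace linking: centroids
  of consecutive MS1 scans chained greedily within `ppm_tol` (default 10
  ppm), traces kept at `min_trace_length >= 3` scans.  No isotope
  deconvolution is attempted, so feature counts are upper bounds on peptide
  features; the identified-feature fraction is the useful quantity.
* Metrics whose inputs are absent (no scan table, no centroids, no sequence
  database) are reported as non-computable with a reason, never as zero.

## 3. The 1–5 score hierarchy

A metric value maps to a score by linear interpolation between a best
threshold (score 5) and a worst threshold (score 1), clamped outside — the
function is monotone, bounded and continuous.  The shipped standards table
anchors the Orbitrap median-MS1-mass-accuracy standard at 1 ppm / 5 ppm; the
other defaults are package choices motivated by the qualitative behaviour of
healthy versus degraded runs (e.g. MS2 identification rate best 0.85 / worst
0.50 — runs near 50 % are exactly the ones whose protein yield collapses;
utilization best 1.5 / worst 0.7; LC delay best 2 / worst 12 min).  Scoring
standards are honestly instrument- and assay-dependent: the table is a
starting point and is fully overridable per `(metric_id, instrument_class)`.

Second-level (metric) scores average into first-level scores per factor of
the decomposition, and those average into the total, with non-computable
metrics excluded rather than imputed; first-level categories are equally
weighted because no principled unequal weighting presents itself.  Scores are
kept real-valued in $[1,5]$; rendering may round.  Metrics scoring below
`flag_threshold = 3` are flagged in the report.

## 4. Cohort metrics and the 2-SD rule

The 23 inter-experiment metrics are: intensity fractions of three
configurable contaminant panels (erythrocyte, cellular debris, serum
high-abundance; shipped lists are curated defaults, not authoritative
panels); median |ΔRT| and the per-run mean of the pairwise retention-time
MSE, $MSE(i,j) = \frac1n \sum_k (RT_{i,k}-RT_{j,k})^2$ over shared
precursors (pairs below `min_shared = 50` shared identifiers are
non-computable); and, at each of precursor / peptide / protein level:
identification count, median log2 intensity, IQR, robust SD, median pairwise
Pearson correlation, and the normalization factor.

Numerical conventions, fixed and documented because the field's usage is
loose:

* **Robust SD** is $1.4826 \times$ MAD (consistent for the normal SD); the
  tests pin it to the `stats::mad` oracle.
* **Normalization factor** is the additive log2 shift of median-shift
  normalization (cohort median of per-run medians minus the run's median) —
  an interpretation, since the term is used in the field without a formula.
* **Per-run Pearson** is the median of the run's pairwise correlations,
  pairwise-complete on shared identifiers.
* **The 2-SD rule** centres on the *median* and spreads by the plain *SD*
  across runs (the common phrase "two standard deviations from the median"
  mixes centre conventions; this pairing is fixed here).  Scores fall
  linearly from 5 at the median to 1 at two SD on the bad side of each
  metric's declared direction (counts and correlations bad-low, spreads and
  contaminant fractions bad-high, normalization factors bad in absolute
  value).  A zero-spread metric scores 5 with no flags.

Because the flag is scale-free, any continuous noise leaves each run a few
percent chance of a flag on each metric — isolated flags are unremarkable by
construction.  The run-level signal is the *count* of flagged metrics:
`flag_low_quality()` reports runs with at least `min_flagged_metrics = 7` of
23, the deviation breadth observed in genuinely failed cohort experiments.

## 5. Normalization algorithms

Three cross-run normalizers operate on log2 intensity matrices and preserve
missingness and within-run rank order: a median shift to the cohort median;
a pairwise-ratio least-squares shift (median log-ratio per run pair, shifts
solved with the first run anchored at zero — the ratio-based flavour of
label-free quantification scaling; a disconnected pair-overlap graph is an
error naming the components); and quantile normalization whose reference is
the mean of order statistics over complete rows, with ties receiving the
mean reference value of their tied ranks.  All three are idempotent to
$10^{-9}$.  Normalization defaults to *off* in the pipeline: the cohort
metrics must see raw systematic bias, and normalized matrices are a separate
output.

## 6. Outlier detection

The 23 × n value matrix (runs as observations) feeds an isolation forest
implemented from the original algorithm: 100 trees, subsample size
$\psi = \min(256, n)$, height limit $\lceil \log_2 \psi \rceil$, uniform
random splits, path lengths adjusted at leaves by
$c(m) = 2H(m-1) - 2(m-1)/m$ and scores $s = 2^{-E(h)/c(\psi)}$.  Two
numerical points: harmonic numbers are computed exactly up to 256 (so
$c(2) = 1$ exactly; the usual $\ln(i)+\gamma$ approximation is wrong by a
factor of six there) and features are standardized to median/IQR with a
half-range fallback when the IQR is zero — a single extreme value in an
otherwise constant metric is precisely what must not be dropped; only truly
constant metrics are removed.

**Decision rule.**  At cohort sizes ($n = \psi \approx 20$) anomaly scores
crowd the 0.5 level — the score an average-path-length point gets — so a
fixed high cutoff misses real faults while the bare 0.5 cut (the automatic
contamination level of the common library implementations) over-flags.  The
package therefore reports a run when the forest isolates it (score > 0.5)
**and** at least `min_explained = 2` of its metrics carry 2-SD flags to
annotate the call — an isolation that no metric corroborates is treated as
forest noise — or, regardless of score, when it trips the
`min_flagged_metrics = 7` run rule.  Union is the default policy,
intersection is available.  These defaults were calibrated on the synthetic
cohorts described below (100-cohort blocks at several disjoint seed ranges)
and are plain arguments of `score_anomalies()` / `detect_outliers()`.

## 7. What the synthetic cohorts emulate — and what they do not

`generate_cohort()` draws a latent catalogue (default 150 proteins, ~4
peptides each, ~15 % with a second charge state) with log-normal intensities
(log2 mean 20, SD 2), uniform retention times over the central 86 % of a
30-minute gradient, and per-run Gaussian RT jitter (SD 0.05 min), a run-level
log2 intensity shift (SD 0.1) plus per-precursor noise (SD 0.3), and a
detection probability of 0.85.  Scan tables use a 2-s duty cycle with the
configured window scheme and a bell-shaped TIC.  Planted anomalies inject
contaminant-panel proteins at an exact target intensity fraction, shift all
RTs by a constant, divide intensities by a factor, or thin identifications.

These choices are modelling conventions, chosen once as plausible for a
urine-like cohort; they are **not** fitted to real data.  The generator has
no isotope structure, no co-elution or interference, no missingness
mechanism beyond detection thinning, no batch structure, and anomalies are
surgical (a real contaminated sample also shifts intensity distributions,
peak shapes and identification rates simultaneously).  Passing the
anomaly-recovery tests therefore shows the pipeline's machinery is sound and
its defaults are coherent under known ground truth — it does not certify
recall on real cohorts, where anomalies are broader but messier.

Problem sizes in the shipped tests were chosen for fast, stable statistics:
worked-example fixtures of 320–1056 MS2 scans, 1000-run identity sweeps with
runs of 20–60 precursors, 100-cohort recovery sweeps at 20 runs × ~700
precursors with scan-table generation disabled (cohort metrics need only the
reports), and 100-seed isolation-forest sweeps at 31 × 2.

## 8. Known limitations

* Vendor raw formats are out of scope; the canonical TSV dialects (plus a
  column map for foreign headers) are the contract.
* The intra-run metric registry is representative, not exhaustive; entries
  whose field definitions are not public (e.g. a spectral signal-to-noise)
  are extension points.
* `directLFQ`/`maxLFQ`-style ion-level protein quantification is not
  re-implemented; the shift/least-squares algorithms above stand in as the
  cross-run bias removers.
* The isolation forest is axis-parallel; an anomaly expressed only as an
  unusual *combination* of individually normal metrics can evade it, and
  anomalies confined to very few metrics rely on the corroboration rule.
* Sequence coverage requires a user-supplied protein database; FDR
  estimation and search are upstream concerns.
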