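Package: mscohort
Title: Quality Control for Large-Cohort LC-MS Proteomics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Intra- and inter-experiment quality control for data-independent
    (DIA) and data-dependent (DDA) acquisition LC-MS proteomics cohorts.
    Decomposes per-run identification output into the multiplicative factors of
    the DIA/DDA scoring models (MS2 identification rate, spectra complexity,
    precursor duplicate-identification rate, MS2 utilization rate), extracts
    scan- and identification-level metrics, maps them onto a configurable 1-5
    linear score hierarchy, computes 23 cohort-level metrics (contaminant-panel
    fractions, retention-time deviation and pairwise mean-squared error, and
    six intensity-distribution statistics at precursor, peptide and
    protein-group level), offers median-shift, pairwise-ratio and quantile
    cross-run normalization, flags runs deviating more than two standard
    deviations from the cohort median, and detects outlier experiments with an
    isolation forest.  A synthetic-cohort generator with planted anomalies
    (contamination, retention-time drift, intensity attenuation, reduced MS2
    identification rate) supports end-to-end validation without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
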