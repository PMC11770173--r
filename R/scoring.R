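#' Define a metric scoring standard
#'
#' A standard maps a metric value to a quality score in \[1, 5\] by linear
#' interpolation between a best threshold (score 5) and a worst threshold
#' (score 1), clamped beyond either.  For `lower_is_better` metrics the best
#' threshold must lie below the worst, and conversely.
#'
#' @param metric_id Metric identifier.
#' @param best_threshold Value at/beyond which the score is 5.
#' @param worst_threshold Value at/beyond which the score is 1.
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @param instrument_class Instrument class the standard applies to
#'   (e.g. `"orbitrap"`, `"tof"`, `"default"`).
#' @return A `score_standard` object.
#' @examples
#' std <- score_standard("median_ms1_mass_accuracy", 1, 5,
#'                       "lower_is_better", "orbitrap")
#' score_metric(c(1, 3, 5), std)   # 5, 3, 1
#' @export
score_standard <- function(metric_id, best_threshold, worst_threshold,
                           direction = c("lower_is_better",
                                         "higher_is_better"),
                           instrument_class = "default") {
  direction <- match.arg(direction)
  if (best_threshold == worst_threshold)
    stop("best_threshold and worst_threshold must differ")
  if (direction == "lower_is_better" && best_threshold > worst_threshold)
    stop("lower_is_better requires best_threshold < worst_threshold")
  if (direction == "higher_is_better" && best_threshold < worst_threshold)
    stop("higher_is_better requires best_threshold > worst_threshold")
  structure(list(metric_id = metric_id, best_threshold = best_threshold,
                 worst_threshold = worst_threshold, direction = direction,
                 instrument_class = instrument_class),
            class = "score_standard")
}

#' Score a metric value on the 1-5 scale
#'
#' Values at or beyond the best threshold score 5, at or beyond the worst
#' threshold score 1, and strictly between the thresholds the score is the
#' linear interpolation `5 - 4 * (value - best) / (worst - best)`.  The
#' function is monotone in the standard's direction and continuous across
#' the thresholds.  Vectorised over `value`; `NA` values (non-computable
#' metrics) yield `NA` scores.
#'
#' @param value Numeric metric value(s).
#' @param standard A [score_standard()].
#' @return Numeric score(s) in \[1, 5\].
#' @export
score_metric <- function(value, standard) {
  stopifnot(inherits(standard, "score_standard"))
  t <- (value - standard$best_threshold) /
    (standard$worst_threshold - standard$best_threshold)
  t <- pmin(pmax(t, 0), 1)
  5 - 4 * t
}

#' Read a scoring-standards table
#'
#' Reads a tab-delimited standards file with columns `metric_id,
#' instrument_class, best_threshold, worst_threshold, direction`.
#'
#' @param path Path to the file; default the standards shipped with the
#'   package.
#' @return Data frame of standards.
#' @export
read_score_standards <- function(path = system.file("extdata",
                                                    "score_standards.tsv",
                                                    package = "mscohort")) {
  std <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("metric_id", "instrument_class", "best_threshold",
            "worst_threshold", "direction")
  stopifnot(all(need %in% names(std)))
  std
}

#' Look up the standard for a metric
#'
#' Prefers an instrument-class-specific entry, then falls back to the
#' `"default"` class.
#'
#' @param standards Data frame from [read_score_standards()].
#' @param metric_id Metric identifier.
#' @param instrument_class Instrument class to prefer.
#' @return A [score_standard()], or `NULL` when no entry exists.
#' @export
lookup_standard <- function(standards, metric_id,
                            instrument_class = "orbitrap") {
  hit <- standards[standards$metric_id == metric_id &
                     standards$instrument_class == instrument_class, ]
  if (!nrow(hit))
    hit <- standards[standards$metric_id == metric_id &
                       standards$instrument_class == "default", ]
  if (!nrow(hit)) return(NULL)
  score_standard(metric_id, hit$best_threshold[1L], hit$worst_threshold[1L],
                 hit$direction[1L], hit$instrument_class[1L])
}

#' Aggregate second-level scores into the score hierarchy
#'
#' Second-level (per-metric) scores are averaged within their first-level
#' category, and the first-level scores are averaged into the total score.
#' Non-computable metrics (`NA` scores) are excluded from their category
#' mean; categories with no computable metric are excluded from the total.
#' For DIA runs the first-level categories are the five factors of the DIA
#' scoring model.
#'
#' @param second_level Named numeric vector of per-metric scores (names are
#'   metric ids; `NA` = non-computable).
#' @param hierarchy Named character vector mapping metric ids to first-level
#'   categories.
#' @param run_id Run identifier carried into the card.
#' @param flag_threshold Metrics scoring below this are flagged (default 3).
#' @return A `score_card` with `second_level`, `first_level`, `total`,
#'   `flags`.
#' @export
aggregate_scores <- function(second_level, hierarchy, run_id = "",
                             flag_threshold = 3) {
  stopifnot(!is.null(names(second_level)))
  unknown <- setdiff(names(second_level), names(hierarchy))
  if (length(unknown))
    stop("metric(s) without a first-level category: ",
         paste(unknown, collapse = ", "))
  cat_of <- hierarchy[names(second_level)]
  first <- c(tapply(second_level, cat_of, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) mean(s) else NA_real_
  }))
  first <- first[!is.na(first)]
  if (!length(first)) stop("no computable metric in any category")
  total <- mean(first)
  flags <- names(second_level)[!is.na(second_level) &
                                 second_level < flag_threshold]
  structure(list(run_id = run_id,
                 second_level = second_level,
                 first_level = unclass(first)[order(names(first))],
                 total = total, flags = flags,
                 flag_threshold = flag_threshold),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> run '%s': total score %.2f / 5\n",
              x$run_id, x$total))
  for (cname in names(x$first_level))
    cat(sprintf("  %-28s %.2f\n", cname, x$first_level[[cname]]))
  if (length(x$flags))
    cat("  flagged (score < ", x$flag_threshold, "): ",
        paste(x$flags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Intra-experiment metric registry
#'
#' The machine-readable catalogue of per-run metrics: id, workflow category
#' (sample, chromatography, dia_windows, ion_source, ms_signal,
#' identification), the first-level scoring factor it informs, unit,
#' direction of goodness and description.
#'
#' @param path Path to a registry TSV; default the registry shipped with the
#'   package.
#' @return Data frame.
#' @export
metric_registry <- function(path = system.file("extdata",
                                               "metric_registry.tsv",
                                               package = "mscohort")) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "\"")
}

#' Score an intra-experiment metric table
#'
#' Applies the scoring standards to every metric row that has a registered
#' standard and aggregates the result into a [aggregate_scores()] score
#' card using the registry's first-level factor assignment.
#'
#' @param metrics Metric data frame from [compute_intra_metrics()].
#' @param standards Standards data frame; default shipped standards.
#' @param instrument_class Instrument class for standard lookup.
#' @param registry Metric registry; default shipped registry.
#' @param flag_threshold Passed to [aggregate_scores()].
#' @return List with `metrics` (input plus a `score` column) and `card`.
#' @export
score_intra_metrics <- function(metrics,
                                standards = read_score_standards(),
                                instrument_class = "orbitrap",
                                registry = metric_registry(),
                                flag_threshold = 3) {
  metrics$score <- NA_real_
  for (i in seq_len(nrow(metrics))) {
    std <- lookup_standard(standards, metrics$metric_id[i], instrument_class)
    if (!is.null(std) && metrics$computable[i])
      metrics$score[i] <- score_metric(metrics$value[i], std)
  }
  scored <- !is.na(metrics$score)
  hierarchy <- stats::setNames(registry$factor, registry$metric_id)
  hierarchy <- hierarchy[!is.na(hierarchy) & nzchar(hierarchy)]
  use <- scored & metrics$metric_id %in% names(hierarchy)
  card <- NULL
  if (any(use)) {
    sl <- stats::setNames(metrics$score[use], metrics$metric_id[use])
    card <- aggregate_scores(sl, hierarchy, run_id = metrics$run_id[1L],
                             flag_threshold = flag_threshold)
  }
  list(metrics = metrics, card = card)
}
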