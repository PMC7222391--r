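# Published DEAP gamma-band reference values, for optional benchmarking.
#
# The reference analysis of the DEAP recordings reports gamma-band cell
# means (mean +/- SD over subjects) and paired-contrast statistics for
# five tree metrics. Reproducing those numbers requires the DEAP
# recordings themselves (a gated download); the tables are encoded here so
# that a user who has run the pipeline on DEAP-shaped input can score
# their metric table against them within the SD-implied tolerance.

#' Published gamma-band benchmark values
#'
#' Reference cell means (+/- SD) per emotion condition and the
#' paired-contrast t and p values reported for the gamma band of the DEAP
#' analysis, for metrics MPLI, maximum degree, leaf fraction, diameter and
#' eccentricity. These are external reference numbers, not quantities this
#' package computes; see [compare_to_published()].
#'
#' @return list with data frames `cells` (`metric`, `condition`, `mean`,
#'   `sd`) and `contrasts` (`metric`, `contrast`, `t`, `p`).
#' @export
published_gamma_benchmarks <- function() {
  cells <- data.frame(
    metric = rep(c("mpli", "degree_max", "leaf_fraction", "diameter",
                   "eccentricity"), each = 4L),
    condition = rep(c("HAHV", "LAHV", "HALV", "LALV"), times = 5L),
    mean = c(0.119, 0.118, 0.121, 0.118,
             0.236, 0.201, 0.270, 0.214,
             0.562, 0.540, 0.593, 0.546,
             0.052, 0.056, 0.048, 0.055,
             0.039, 0.042, 0.037, 0.042),
    sd = c(0.0017, 0.0033, 0.0027, 0.0032,
           0.037, 0.024, 0.052, 0.036,
           0.035, 0.056, 0.052, 0.048,
           0.0045, 0.0071, 0.0045, 0.0062,
           0.0034, 0.0051, 0.0033, 0.0048),
    stringsAsFactors = FALSE)
  contrasts <- data.frame(
    metric = rep(c("mpli", "degree_max", "leaf_fraction", "diameter",
                   "eccentricity"), each = 4L),
    contrast = rep(c("HAHV-LAHV", "HALV-LALV", "HAHV-HALV", "LAHV-LALV"),
                   times = 5L),
    t = c(2.326, 5.572, -4.752, -0.175,
          6.227, 5.903, -4.467, -2.345,
          2.658, 5.218, -3.537, -0.671,
          -5.584, -6.942, 7.448, 1.048,
          -5.609, -6.848, 8.096, 1.148),
    p = c(0.036, 0, 0, 0.862,
          0, 0, 0, 0.026,
          0.016, 0, 0.002, 0.507,
          0, 0, 0, 0.303,
          0, 0, 0, 0.26),
    stringsAsFactors = FALSE)
  list(cells = cells, contrasts = contrasts)
}

#' Expected direction of the arousal contrast
#'
#' The sign pattern of HAHV - LAHV (high minus low arousal at high
#' valence) in the gamma band: connectivity strength, hubness and leafiness
#' rise with arousal while the tree's extent shrinks.
#'
#' @return named numeric vector of +/-1 per metric.
#' @export
arousal_direction_pattern <- function() {
  c(mpli = 1, degree_max = 1, leaf_fraction = 1,
    diameter = -1, eccentricity = -1)
}

#' Score a metric table against the published benchmarks
#'
#' Joins a gamma-band metric table's cell means with the published
#' reference means and reports a z-score per cell,
#' `(observed - reference) / reference SD`, plus whether it falls within
#' `tol_sd` reference SDs. Only meaningful for pipelines run on the real
#' DEAP recordings; on synthetic data the report documents the (expected)
#' discrepancy.
#'
#' @param metric_table long metric table.
#' @param band band to score (default `"gamma"`).
#' @param tol_sd tolerance in reference-SD units (default 2).
#' @return data frame with observed and reference means, `z` and `within`.
#' @export
compare_to_published <- function(metric_table, band = "gamma", tol_sd = 2) {
  ref <- published_gamma_benchmarks()$cells
  sl <- metric_table[metric_table$band == band &
                       metric_table$metric %in% unique(ref$metric), ]
  if (nrow(sl) == 0L) stop("metric table has no rows for band '", band, "'")
  obs <- stats::aggregate(value ~ metric + condition, sl, mean)
  out <- merge(ref, obs, by = c("metric", "condition"), all.x = TRUE)
  names(out)[names(out) == "value"] <- "observed"
  out$z <- (out$observed - out$mean) / out$sd
  out$within <- !is.na(out$z) & abs(out$z) <= tol_sd
  out[order(out$metric, out$condition), ]
}
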