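# Group-level inference: 2x2 within-subject ANOVA, paired contrasts, FDR.

#' Long-format metric table utilities
#'
#' The inferential layer consumes a long data frame with columns
#' `subject_id`, `condition` (HAHV/HALV/LAHV/LALV), `band`, `metric`,
#' `value` — one value per subject x condition x band x metric.
#' @name metric-table
NULL

# Reshape one metric x band slice to a complete subject x condition matrix,
# dropping (and logging) subjects with incomplete cells.
complete_cells <- function(table, metric, band) {
  sl <- table[table$metric == metric & table$band == band, , drop = FALSE]
  if (nrow(sl) == 0L) stop("no rows for metric '", metric, "' in band '",
                           band, "'")
  conds <- emotion_conditions()
  wide <- matrix(NA_real_, nrow = length(unique(sl$subject_id)),
                 ncol = 4L, dimnames = list(unique(sl$subject_id), conds))
  for (r in seq_len(nrow(sl))) {
    if (!sl$condition[r] %in% conds) next
    wide[as.character(sl$subject_id[r]), sl$condition[r]] <- sl$value[r]
  }
  complete <- stats::complete.cases(wide)
  dropped <- rownames(wide)[!complete]
  if (length(dropped) > 0L)
    message("dropping subject(s) with incomplete cells: ",
            paste(dropped, collapse = ", "))
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3L)
    stop("fewer than 3 subjects with complete 2x2 data")
  wide
}

#' 2x2 within-subject (repeated measures) ANOVA
#'
#' Two-factor fully within-subject ANOVA on one metric in one band, with
#' factors arousal (high/low) and valence (high/low). Each effect is
#' tested against its own subject-by-effect error stratum (the standard
#' repeated-measures decomposition; with two levels per factor sphericity
#' holds trivially). Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table long metric table (see [study_metric_table()]).
#' @param metric metric name.
#' @param band band name.
#' @return data frame with one row per effect (`arousal`, `valence`,
#'   `interaction`): `F`, `df_effect`, `df_error`, `p`, `es`.
#' @export
rm_anova_2x2 <- function(table, metric, band) {
  wide <- complete_cells(table, metric, band)
  ns <- nrow(wide)
  long <- data.frame(
    value = as.vector(wide),
    subject = factor(rep(rownames(wide), times = 4L)),
    arousal = factor(rep(substr(colnames(wide), 1, 1), each = ns)),
    valence = factor(rep(substr(colnames(wide), 3, 3), each = ns))
  )
  fit <- stats::aov(value ~ arousal * valence +
                      Error(subject / (arousal * valence)), data = long)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    rn <- trimws(rownames(tab))
    k <- match(term, rn)
    resid <- match("Residuals", rn)
    ss_e <- tab[k, "Sum Sq"]; ss_r <- tab[resid, "Sum Sq"]
    f <- tab[k, "F value"]; p <- tab[k, "Pr(>F)"]
    tiny <- 1e-12 * max(ss_e, ss_r, 1)
    if (!is.finite(ss_r) || ss_r < tiny) {
      # degenerate noiseless case: effect variance with zero error
      f <- if (ss_e >= tiny) Inf else 0
      p <- if (ss_e >= tiny) 0 else 1
      if (ss_e < tiny) ss_e <- 0
    }
    es <- if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0
    data.frame(F = f, df_effect = tab[k, "Df"], df_error = tab[resid, "Df"],
               p = p, es = es)
  }
  out <- rbind(pull("Error: subject:arousal", "arousal"),
               pull("Error: subject:valence", "valence"),
               pull("Error: subject:arousal:valence", "arousal:valence"))
  out <- cbind(data.frame(metric = metric, band = band,
                          effect = c("arousal", "valence", "interaction"),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Paired t-tests on the four condition contrasts
#'
#' Subject-matched two-sided paired t-tests for the fixed contrasts
#' HAHV-LAHV, HALV-LALV (arousal within valence level) and HAHV-HALV,
#' LAHV-LALV (valence within arousal level). A zero-variance difference
#' leaves t undefined (reported as NA).
#'
#' @param table long metric table.
#' @param metric metric name.
#' @param band band name.
#' @return data frame with columns `metric`, `band`, `contrast`, `t`,
#'   `df`, `p_raw`, `mean_diff`.
#' @export
paired_contrasts <- function(table, metric, band) {
  wide <- complete_cells(table, metric, band)
  pairs <- list(`HAHV-LAHV` = c("HAHV", "LAHV"),
                `HALV-LALV` = c("HALV", "LALV"),
                `HAHV-HALV` = c("HAHV", "HALV"),
                `LAHV-LALV` = c("LAHV", "LALV"))
  rows <- lapply(names(pairs), function(cn) {
    a <- wide[, pairs[[cn]][1L]]; b <- wide[, pairs[[cn]][2L]]
    d <- a - b
    if (sd(d) < 1e-14) {
      t_val <- NA_real_; p <- NA_real_
    } else {
      tt <- t.test(a, b, paired = TRUE)
      t_val <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(metric = metric, band = band, contrast = cn, t = t_val,
               df = length(d) - 1L, p_raw = p, mean_diff = mean(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p * m / rank` with monotonicity enforced
#' from the largest p downward, capped at 1. Never decreases a p-value;
#' invariant to input order as a multiset.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04, 0.5))
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full inferential layer over a metric table
#'
#' Runs the 2x2 within-subject ANOVA and the four paired contrasts for
#' every metric x band present in the table, and FDR-adjusts contrast
#' p-values. The adjustment family is, per band, the four contrasts of one
#' metric (`fdr_family = "per_metric"`) or all contrasts of all metrics
#' pooled (`"pooled"`).
#'
#' @param table long metric table from [study_metric_table()].
#' @param fdr_family `"per_metric"` or `"pooled"`.
#' @return list with data frames `anova` and `contrasts` (the latter with
#'   `p_fdr`), plus `cell_means` (mean and SD per condition).
#' @export
condition_stats <- function(table, fdr_family = c("per_metric", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(all(c("subject_id", "condition", "band", "metric", "value")
                %in% names(table)))
  combos <- unique(table[, c("metric", "band")])
  an <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k)
    rm_anova_2x2(table, combos$metric[k], combos$band[k])))
  ct <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k)
    paired_contrasts(table, combos$metric[k], combos$band[k])))
  if (fdr_family == "per_metric") {
    ct$p_fdr <- NA_real_
    for (k in seq_len(nrow(combos))) {
      sel <- ct$metric == combos$metric[k] & ct$band == combos$band[k]
      ct$p_fdr[sel] <- fdr_adjust(ct$p_raw[sel])
    }
  } else {
    for (b in unique(ct$band)) {
      sel <- ct$band == b
      ct$p_fdr[sel] <- fdr_adjust(ct$p_raw[sel])
    }
  }
  agg_mean <- stats::aggregate(value ~ metric + band + condition, table, mean)
  agg_sd <- stats::aggregate(value ~ metric + band + condition, table, sd)
  names(agg_mean)[4] <- "mean"; agg_mean$sd <- agg_sd$value
  list(anova = an, contrasts = ct, cell_means = agg_mean)
}
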