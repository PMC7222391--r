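# From a classified study to per-subject condition matrices, trees and the
# long metric table the inferential layer consumes.

#' Analyze a study: matrices, trees and tree metrics
#'
#' For every retained subject, emotion condition and requested band:
#' computes per-trial PLI matrices, averages them into one condition
#' matrix, builds its maximum-weight spanning tree, and evaluates the tree
#' metrics. Two aggregation modes are available: `"matrix-average"`
#' (default) averages trial PLI matrices first and computes one tree and
#' one set of metrics per condition; `"trial-metric-average"` computes a
#' tree and metrics per trial and averages the metric values. The
#' condition-average matrix and its tree are produced in both modes (they
#' feed the group-level average tree).
#'
#' @param study a classified study (see [classify_study()]); trials whose
#'   condition is UNCLASSIFIED are ignored.
#' @param bands character vector of band names (or list of
#'   [band_definition()]s).
#' @param aggregation `"matrix-average"` or `"trial-metric-average"`.
#' @param edge_trim seconds trimmed per end before PLI.
#' @param distance distance convention for tree metrics.
#' @return list with `metric_table` (long data frame), `matrices` and
#'   `trees` (nested lists indexed `[[band]][[subject]][[condition]]`).
#' @export
analyze_study <- function(study, bands = "gamma",
                          aggregation = c("matrix-average",
                                          "trial-metric-average"),
                          edge_trim = 0.5,
                          distance = c("weighted", "hop")) {
  aggregation <- match.arg(aggregation)
  distance <- match.arg(distance)
  if (is.character(bands)) bands <- lapply(bands, as_band)
  if (inherits(bands, "band_definition")) bands <- list(bands)
  subs <- study_subjects(study)
  if (length(subs) == 0L) stop("empty study")
  rows <- list()
  matrices <- list(); trees <- list()
  for (band in bands) {
    bname <- band$name
    matrices[[bname]] <- list(); trees[[bname]] <- list()
    for (sub in subs) {
      sid <- as.character(sub$subject_id)
      if (is.null(sub$labels$condition))
        stop("study is not classified; run classify_study() first")
      matrices[[bname]][[sid]] <- list()
      trees[[bname]][[sid]] <- list()
      for (cond in emotion_conditions()) {
        tsel <- which(sub$labels$condition == cond)
        if (length(tsel) == 0L) next
        trial_ids <- sub$labels$trial_id[tsel]
        mats <- lapply(trial_ids, function(tid) {
          tr <- sub$trials[[match(tid, vapply(sub$trials,
                                              function(x) x$trial_id,
                                              numeric(1)))]]
          trial_pli(tr, band, edge_trim = edge_trim, condition = cond)
        })
        cmat <- condition_matrix(mats)
        cmat$condition <- cond
        ctree <- max_spanning_tree(cmat)
        matrices[[bname]][[sid]][[cond]] <- cmat
        trees[[bname]][[sid]][[cond]] <- ctree
        if (aggregation == "matrix-average") {
          met <- tree_metrics(ctree, mpli = mean_pli(cmat),
                              distance = distance)
          vals <- unlist(met[tree_metric_names()])
        } else {
          per_trial <- vapply(mats, function(m) {
            tm <- tree_metrics(max_spanning_tree(m), mpli = mean_pli(m),
                               distance = distance)
            unlist(tm[tree_metric_names()])
          }, numeric(length(tree_metric_names())))
          vals <- rowMeans(per_trial)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, band = bname,
          metric = tree_metric_names(), value = unname(vals),
          stringsAsFactors = FALSE)
      }
    }
  }
  metric_table <- do.call(rbind, rows)
  rownames(metric_table) <- NULL
  list(metric_table = metric_table, matrices = matrices, trees = trees)
}

#' Long metric table of a study
#'
#' Convenience wrapper around [analyze_study()] returning only the long
#' subject x condition x band x metric table.
#'
#' @inheritParams analyze_study
#' @return data frame with columns `subject_id`, `condition`, `band`,
#'   `metric`, `value`.
#' @export
study_metric_table <- function(study, bands = "gamma",
                               aggregation = c("matrix-average",
                                               "trial-metric-average"),
                               edge_trim = 0.5,
                               distance = c("weighted", "hop")) {
  analyze_study(study, bands = bands, aggregation = aggregation,
                edge_trim = edge_trim, distance = distance)$metric_table
}
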