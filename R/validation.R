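# Simulation-based calibration of the full analysis chain. These run the
# generator and the estimation path end to end many times; the problem
# sizes (5-s trials, one trial per condition) are the smallest the PLI
# sample-size contract admits, which keeps replicate counts high.

#' Type-I error rate of the arousal test under the null
#'
#' Simulates `n_reps` studies with all condition effects at zero, runs the
#' connectivity path (gamma band), and tests the arousal main effect on
#' whole-network mean PLI with the 2x2 within-subject ANOVA. Returns the
#' fraction of replicates rejecting at `alpha` — nominally `alpha` itself
#' when the chain is well calibrated.
#'
#' @param n_reps number of null replicates (default 200).
#' @param n_subjects subjects per replicate (default 20).
#' @param duration trial length in seconds (default 5, the shortest
#'   length satisfying the PLI sample-size contract after edge trimming).
#' @param alpha nominal test level.
#' @param seed RNG seed.
#' @return the rejection rate, with attribute `p_values`.
#' @export
null_rejection_rate <- function(n_reps = 200L, n_subjects = 20L,
                                duration = 5, alpha = 0.05, seed = 1L) {
  seeds <- derive_seeds(seed, n_reps)
  p_values <- vapply(seq_len(n_reps), function(r) {
    cfg <- group_sim_config(n_subjects = n_subjects,
                            trials_per_condition = 1L,
                            duration = duration,
                            arousal_effect = 0, valence_effect = 0,
                            interaction_effect = 0, seed = seeds[r])
    study <- generate_group(cfg)
    rows <- lapply(study$subjects, function(sub) {
      data.frame(subject_id = as.character(sub$subject_id),
                 condition = sub$labels$condition,
                 band = "gamma", metric = "mpli",
                 value = vapply(sub$trials, function(tr)
                   mean_pli(trial_pli(tr, "gamma")), numeric(1)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    an <- rm_anova_2x2(tab, "mpli", "gamma")
    an$p[an$effect == "arousal"]
  }, numeric(1))
  structure(mean(p_values < alpha), p_values = p_values)
}

#' Recovery rate of the planted arousal direction pattern
#'
#' Simulates studies with a planted arousal effect on coupling and checks,
#' per replicate, whether the high-minus-low-arousal difference of the
#' subject-mean metrics carries the expected sign for all five benchmark
#' metrics ([arousal_direction_pattern()]): MPLI, maximum degree and leaf
#' fraction up; diameter and eccentricity down.
#'
#' @param n_reps number of replicates (default 50).
#' @param n_subjects subjects per replicate (default 12).
#' @param arousal_effect planted additive coupling delta (default 0.3).
#' @param duration trial length in seconds.
#' @param seed RNG seed.
#' @return fraction of replicates recovering the full sign pattern, with
#'   attribute `per_metric` (per-metric recovery rates).
#' @export
direction_recovery_rate <- function(n_reps = 50L, n_subjects = 12L,
                                    arousal_effect = 0.3, duration = 5,
                                    seed = 1L) {
  seeds <- derive_seeds(seed, n_reps)
  dir <- arousal_direction_pattern()
  hits <- matrix(FALSE, n_reps, length(dir),
                 dimnames = list(NULL, names(dir)))
  for (r in seq_len(n_reps)) {
    cfg <- group_sim_config(n_subjects = n_subjects,
                            trials_per_condition = 1L,
                            duration = duration,
                            arousal_effect = arousal_effect,
                            valence_effect = 0, interaction_effect = 0,
                            seed = seeds[r])
    tab <- study_metric_table(classify_study(generate_group(cfg)),
                              bands = "gamma")
    for (m in names(dir)) {
      sl <- tab[tab$metric == m, ]
      hi <- tapply(sl$value[sl$condition %in% c("HAHV", "HALV")],
                   sl$subject_id[sl$condition %in% c("HAHV", "HALV")], mean)
      lo <- tapply(sl$value[sl$condition %in% c("LAHV", "LALV")],
                   sl$subject_id[sl$condition %in% c("LAHV", "LALV")], mean)
      hits[r, m] <- sign(mean(hi - lo)) == dir[[m]]
    }
  }
  structure(mean(apply(hits, 1L, all)), per_metric = colMeans(hits))
}
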