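# The inferential layer: 2x2 within-subject ANOVA, paired contrasts, FDR.

hand_table <- function() {
  # 6 subjects, additive arousal shift + valence wiggle + noise
  set.seed(61)
  base <- rnorm(6, 10, 1)
  wide <- cbind(HAHV = base + 1.0 + rnorm(6, 0, 0.3),
                HALV = base + 1.2 + rnorm(6, 0, 0.3),
                LAHV = base + 0.0 + rnorm(6, 0, 0.3),
                LALV = base + 0.3 + rnorm(6, 0, 0.3))
  rownames(wide) <- paste0("s", 1:6)
  wide
}

test_that("ANOVA F, p and partial eta squared match a from-scratch SS oracle", {
  wide <- hand_table()
  got <- rm_anova_2x2(wide_to_table(wide), "mpli", "gamma")
  oracle <- manual_rm_anova(wide)
  for (eff in c("arousal", "valence", "interaction")) {
    row <- got[got$effect == eff, ]
    expect_equal(row$F, oracle[[eff]]$F, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(row$p, oracle[[eff]]$p, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(row$es, oracle[[eff]]$es, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(row$df_effect, 1)
    expect_equal(row$df_error, 5)
  }
})

test_that("ANOVA degenerate cases behave", {
  # all values identical: F = 0 everywhere
  flat <- matrix(3, 5, 4, dimnames = list(paste0("s", 1:5),
                                          emotion_conditions()))
  got <- rm_anova_2x2(wide_to_table(flat), "mpli", "gamma")
  expect_equal(got$F, rep(0, 3))
  # additive arousal shift with zero noise: error SS vanishes
  base <- 1:5
  shifted <- cbind(HAHV = base + 1, HALV = base + 1, LAHV = base,
                   LALV = base)
  colnames(shifted) <- c("HAHV", "HALV", "LAHV", "LALV")
  rownames(shifted) <- paste0("s", 1:5)
  got2 <- rm_anova_2x2(wide_to_table(shifted), "mpli", "gamma")
  ar <- got2[got2$effect == "arousal", ]
  expect_true(is.infinite(ar$F))
  expect_equal(ar$p, 0)
  expect_equal(ar$es, 1)
})

test_that("subjects with incomplete cells are dropped; too few error", {
  wide <- hand_table()
  tab <- wide_to_table(wide)
  tab <- tab[!(tab$subject_id == "s6" & tab$condition == "LALV"), ]
  expect_message(got <- rm_anova_2x2(tab, "mpli", "gamma"), "s6")
  expect_equal(got$df_error[1], 4)  # 5 complete subjects
  tab2 <- wide_to_table(wide[1:2, ])
  expect_error(rm_anova_2x2(tab2, "mpli", "gamma"), "fewer than 3")
})

test_that("paired t equals its closed form on hand-made vectors", {
  wide <- hand_table()
  got <- paired_contrasts(wide_to_table(wide), "mpli", "gamma")
  expect_setequal(got$contrast,
                  c("HAHV-LAHV", "HALV-LALV", "HAHV-HALV", "LAHV-LALV"))
  for (k in seq_len(nrow(got))) {
    parts <- strsplit(got$contrast[k], "-")[[1]]
    d <- wide[, parts[1]] - wide[, parts[2]]
    t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(got$t[k], t_closed, tolerance = 1e-12)
    p_closed <- 2 * pt(abs(t_closed), df = length(d) - 1, lower.tail = FALSE)
    expect_equal(got$p_raw[k], p_closed, tolerance = 1e-12)
  }
})

test_that("identical and zero-variance pairs hit the degenerate paths", {
  wide <- hand_table()
  same <- wide; same[, "LAHV"] <- same[, "HAHV"]  # identical paired vectors
  got <- paired_contrasts(wide_to_table(same), "mpli", "gamma")
  expect_true(is.na(got$t[got$contrast == "HAHV-LAHV"]))
  # constant nonzero difference: t undefined (SD of differences is 0)
  shift <- wide; shift[, "LAHV"] <- shift[, "HAHV"] - 1
  got2 <- paired_contrasts(wide_to_table(shift), "mpli", "gamma")
  expect_true(is.na(got2$t[got2$contrast == "HAHV-LAHV"]))
  expect_equal(got2$mean_diff[got2$contrast == "HAHV-LAHV"], 1)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(fdr_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH never lowers a p-value and ignores input order", {
  set.seed(8)
  for (k in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- fdr_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(sort(fdr_adjust(p[perm])), sort(adj))
  }
})

test_that("condition_stats assembles ANOVA, contrasts and FDR families", {
  wide <- hand_table()
  tab <- rbind(wide_to_table(wide, metric = "mpli"),
               wide_to_table(wide * 2, metric = "leaf_fraction"))
  st <- condition_stats(tab)
  expect_equal(nrow(st$anova), 6L)   # 2 metrics x 3 effects
  expect_equal(nrow(st$contrasts), 8L)
  # per-metric family: adjustment within each metric's four contrasts
  m1 <- st$contrasts[st$contrasts$metric == "mpli", ]
  expect_equal(m1$p_fdr, fdr_adjust(m1$p_raw))
  expect_equal(nrow(st$cell_means), 8L)
  # scaling a metric by 2 leaves t and p identical
  expect_equal(st$contrasts$t[st$contrasts$metric == "mpli"],
               st$contrasts$t[st$contrasts$metric == "leaf_fraction"])
})
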