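test_that("identical groups are not declared different by one-tailed tests", {
  x <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  res <- compare_groups(list(a = x, b = x),
                        design = list(test = "t", alternative = "greater"))
  expect_gte(res$p_value, 0.5)
  res2 <- compare_groups(list(a = x, b = x),
                         design = list(test = "mann_whitney",
                                       alternative = "greater"))
  expect_gte(res2$p_value, 0.45)
})

test_that("one-tailed direction must be declared, never inferred", {
  expect_error(compare_groups(list(a = 1:5, b = 6:10),
                              design = list(test = "t")), "declare")
  expect_error(compare_groups(list(a = c(4, 6), b = c(1, 8)),
                              design = list(test = "chisq_2x2")), "declare")
})

test_that("one-sided 2x2 chi-square agrees with the exact hypergeometric oracle", {
  tab <- rbind(a = c(8, 2), b = c(2, 8))
  res <- compare_groups(tab, design = list(test = "chisq_2x2",
                                           alternative = "greater"))
  expect_lt(res$p_value, 0.05)
  # hypergeometric oracle: P(X >= 8) drawing 10 from 10 successes in 20
  p_exact <- stats::phyper(8 - 1, 10, 10, 10, lower.tail = FALSE)
  expect_lt(p_exact, 0.05)
  # across random 2x2 tables: valid p, and clearly-significant exact results
  # are also called by the (anti-conservative) one-sided chi-square
  set.seed(7)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 6) + 1, 2, 2)
    z <- compare_groups(t2, design = list(test = "chisq_2x2",
                                          alternative = "greater"))
    f <- stats::fisher.test(t2, alternative = "greater")
    expect_true(z$p_value >= 0 && z$p_value <= 1)
    if (f$p.value < 0.01) expect_lt(z$p_value, 0.05)
  }
})

test_that("parametric designs refuse n < 2 and report exact n", {
  expect_error(compare_groups(list(a = 1, b = c(1, 2)),
                              design = list(test = "t", alternative = "less")),
               "n >= 2")
  res <- compare_groups(list(a = c(1, 2, 3), b = c(2, 3, 4, 5)),
                        design = list(test = "t", alternative = "less"))
  expect_identical(unname(res$n), c(3L, 4L))
})

test_that("ANOVA post hoc families run against the declared control", {
  set.seed(11)
  vals <- list(ctrl = rnorm(8, 10), lo = rnorm(8, 10.2), hi = rnorm(8, 13))
  dn <- compare_groups(vals, design = list(test = "anova_dunnett",
                                           control = "ctrl"))
  expect_identical(nrow(dn$posthoc), 2L)
  expect_true(any(dn$posthoc$p_adjusted < 0.01))
  hs <- compare_groups(vals, design = list(test = "anova_holm_sidak",
                                           control = "ctrl"))
  expect_true(all(hs$posthoc$p_adjusted >= hs$posthoc$p_value - 1e-12))
  kd <- compare_groups(vals, design = list(test = "kruskal_dunn",
                                           control = "ctrl"))
  expect_identical(nrow(kd$posthoc), 2L)
  expect_true(all(kd$posthoc$p_adjusted <= 1))
})

test_that("Holm-Sidak adjustment is a monotone step-down Sidak", {
  p <- c(0.01, 0.04, 0.3, 0.8)
  adj <- fretbench:::holm_sidak_adjust(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^4, tolerance = 1e-12)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
})

test_that("MAD outlier rule excludes gross outliers, keeps clean data", {
  r <- remove_outliers(c(1, 1.1, 0.9, 1.0, 50))
  expect_identical(r$excluded, 50)
  expect_identical(r$kept, c(1, 1.1, 0.9, 1.0))
  same <- remove_outliers(rep(2, 6))
  expect_length(same$excluded, 0L)
  set.seed(99)
  mc <- remove_outliers(rnorm(1000))
  expect_lt(length(mc$excluded) / 1000, 0.02)
  expect_error(remove_outliers(1:3), ">= 4")
  expect_error(remove_outliers(1:10, method = "rout"), "unknown")
})

test_that("genotype effect is detected with high power at cohort defaults", {
  # truth-level power check: margin activity draws at n = 8 per group
  reps <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    cfg <- noonan_cohort_config(n_embryos = 8, seed = 1000 + r)
    coh <- make_cohort(cfg, render = character(0))
    v <- split(coh$truth$margin_efficiency, coh$truth$group)
    p <- compare_groups(v[c("Shp2D61G", "Shp2WT")],
                        design = list(test = "t", alternative = "greater"))$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("summary matrix joins levels and orders medians by construction", {
  mol <- data.frame(embryo_id = sprintf("e%d", 1:6),
                    group = rep(c("WT", "D61G"), each = 3),
                    E_percent = c(10, 11, 12, 25, 26, 27))
  mol$R_DA_nm <- distance_from_efficiency(mol$E_percent / 100)
  morph <- data.frame(embryo_id = sprintf("e%d", 1:6),
                      group = rep(c("WT", "D61G"), each = 3),
                      axis_ratio = c(1.3, 1.31, 1.29, 1.6, 1.59, 1.61),
                      body_length = c(110, 111, 109, 88, 87, 89))
  sm <- summary_matrix(mol, morph, groups = c("WT", "D61G"))
  expect_identical(nrow(sm$per_embryo), 6L)
  expect_true(all(c("E_percent", "R_DA_nm", "axis_ratio", "body_length")
                  %in% names(sm$per_embryo)))
  # R_DA decreases where E increases
  expect_lt(sm$group_medians$R_DA_nm[2], sm$group_medians$R_DA_nm[1])
  # unmatched morphological labels are an error naming the label
  bad <- morph; bad$group[1] <- "Mystery"
  expect_error(summary_matrix(mol, bad), "Mystery")
  # molecular-only fallback warns
  expect_warning(summary_matrix(mol, NULL), "molecular-only")
})
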