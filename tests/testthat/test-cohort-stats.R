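test_that("two-sample proportion test reproduces printed baseline p-values", {
  # primary tumor location: 12/12 vs 25/37 positive-left
  expect_equal(signif(two_proportion_test(12, 12, 25, 37)$p_value, 2), 0.023)
  # number of liver metastases: 4/12 vs 25/37 with a single metastasis
  expect_equal(signif(two_proportion_test(4, 12, 25, 37)$p_value, 2), 0.036)
  # equal proportions -> z = 0, p = 1
  eq <- two_proportion_test(5, 10, 10, 20)
  expect_equal(eq$z, 0); expect_equal(eq$p_value, 1)
  expect_error(two_proportion_test(1, 0, 2, 5), "zero total")
})

test_that("two-proportion test is antisymmetric in the groups", {
  set.seed(3)
  for (r in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x1 <- rbinom(1, n1, 0.4); x2 <- rbinom(1, n2, 0.7)
    a <- two_proportion_test(x1, n1, x2, n2)
    b <- two_proportion_test(x2, n2, x1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("median test matches a hand-built corrected 2x2 chi-square", {
  g1 <- c(1.2, 3.4, 2.2, 5.6, 0.4, 4.4, 2.9, 3.3, 1.8, 2.5)
  g2 <- c(4.1, 6.2, 5.5, 7.3, 3.9, 8.0, 4.8, 5.1, 6.6, 2.0)
  res <- median_test(list(g1, g2))
  # oracle: classify against the grand median, Yates-corrected chi-square
  med <- median(c(g1, g2))
  o <- rbind(c(sum(g1 > med), sum(g2 > med)),
             c(sum(g1 <= med), sum(g2 <= med)))
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2_oracle <- sum((pmax(abs(o - e) - 0.5, 0))^2 / e)
  expect_equal(res$chi2, chi2_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(chi2_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # and against stats::chisq.test on the same table
  ref <- suppressWarnings(chisq.test(o, correct = TRUE))
  expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-12)

  # identical groups -> p ~ 1; identical values -> p = 1 exactly
  same <- median_test(list(g1, g1))
  expect_gt(same$p_value, 0.9)
  flat <- median_test(list(rep(2, 5), rep(2, 7)))
  expect_equal(flat$chi2, 0); expect_equal(flat$p_value, 1)

  # full separation at n = 20 per group
  sep <- median_test(list(1:20, 41:60))
  expect_lt(sep$p_value, 0.001)
  expect_error(median_test(list(1:3)), "at least 2 groups")
})

test_that("Bonferroni thresholds match the quoted table footnote", {
  expect_equal(bonferroni_threshold(0.05, 11), 0.0045)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 6), 0.0083)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("fisher power behaves at the design extremes", {
  # null design: power stays near alpha
  null_pw <- fisher_power(rfs_pos = 0.5, rfs_neg = 0.5, n_reps = 2000,
                          seed = 6)
  expect_lte(null_pw$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
  # perfect separation: power ~ 1
  sep_pw <- fisher_power(n_enrolled = 25, dropout_rate = 0.2,
                         rfs_pos = 0, rfs_neg = 1, n_reps = 2000, seed = 7)
  expect_gt(sep_pw$power, 0.99)
  expect_equal(sep_pw$n_analyzable, 20)
  # monotone in the effect size at three grid points
  p1 <- fisher_power(rfs_pos = 0.4, rfs_neg = 0.6, n_reps = 3000, seed = 8)
  p2 <- fisher_power(rfs_pos = 0.3, rfs_neg = 0.8, n_reps = 3000, seed = 8)
  p3 <- fisher_power(rfs_pos = 0.1, rfs_neg = 0.95, n_reps = 3000, seed = 8)
  expect_lte(p1$power, p2$power + 0.02)
  expect_lte(p2$power, p3$power + 0.02)
  expect_error(fisher_power(n_reps = 100), "n_reps")
})

test_that("transition table reproduces the serial adjuvant fixture", {
  # 36 patients with both TP and TEOT calls: 11 TP-positive of whom 3 clear
  # (2 of the 3 stay recurrence-free), 8 persistently positive all recurring,
  # 2 convert to positive and recur, 23 negative at both (2 recur)
  calls <- data.frame(
    patient_id = sprintf("P%02d", 1:38),
    tp_pos = c(rep(TRUE, 11), rep(FALSE, 25), TRUE, NA),
    teot_pos = c(rep(FALSE, 3), rep(TRUE, 8), rep(TRUE, 2), rep(FALSE, 23),
                 NA, TRUE),
    recurred = c(FALSE, FALSE, TRUE, rep(TRUE, 8), TRUE, TRUE,
                 rep(c(TRUE, FALSE), c(2, 21)), FALSE, TRUE))
  tab <- transitions_table(calls)
  expect_equal(tab$n[tab$category == "TP+/TEOT-"], 3L)
  expect_equal(tab$n[tab$category == "TP+/TEOT+"], 8L)
  expect_equal(tab$n[tab$category == "TP-/TEOT+"], 2L)
  expect_equal(tab$n[tab$category == "TP-/TEOT-"], 23L)
  expect_equal(sum(tab$n), 36L)  # counts sum to complete-pair patients
  expect_equal(tab$n_recurred[tab$category == "TP+/TEOT+"], 8L)
  expect_equal(tab$n_recurred[tab$category == "TP-/TEOT+"], 2L)
  expect_length(attr(tab, "excluded"), 2)

  # empty input and single-category input
  empty <- transitions_table(calls[0, ])
  expect_true(all(empty$n == 0))
  allneg <- transitions_table(data.frame(patient_id = "X", tp_pos = FALSE,
                                         teot_pos = FALSE, recurred = FALSE))
  expect_equal(sum(allneg$n), 1L)
  expect_equal(allneg$n[allneg$category == "TP-/TEOT-"], 1L)
})

test_that("MAF quartile strata follow the <= cut-off convention", {
  expect_equal(as.character(maf_quartile_strata(0.15)), "Q1")
  expect_equal(as.character(maf_quartile_strata(0.5)), "Q2")
  expect_equal(as.character(maf_quartile_strata(1.04)), "Q2")
  expect_equal(as.character(maf_quartile_strata(7.2)), "Q3")
  expect_equal(as.character(maf_quartile_strata(100)), "Q4")
  expect_equal(as.character(maf_quartile_strata(0)), "Q1")
  expect_error(maf_quartile_strata(-1), "negative")
})

test_that("baseline association table mixes the two tests appropriately", {
  set.seed(20)
  n <- 60
  pats <- data.frame(age_years = rnorm(n, 64, 10),
                     synchronous = rbinom(n, 1, 0.5),
                     interval_gt12m = rbinom(n, 1, 0.4),
                     cea_baseline_elevated = rbinom(n, 1, 0.5))
  status <- rbinom(n, 1, 0.8) == 1
  tab <- baseline_assoc_table(pats, status)
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$test), c("median", "two-proportion"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(attr(tab, "bonferroni_threshold"),
               bonferroni_threshold(0.05, 4))
})
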