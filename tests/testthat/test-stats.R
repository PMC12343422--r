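test_that("staging follows the FIB-4 / decompensation rule", {
  expect_equal(classify_stage(list(fib4 = 3.5))$group, "ACLD")
  s <- classify_stage(list(fib4 = 0.8))
  expect_equal(s$group, "non-ACLD")
  expect_equal(s$fib4_category, "low")
  # decompensation overrides a low score ("and/or" rule)
  s2 <- classify_stage(list(fib4 = 1.0), decompensated = TRUE)
  expect_equal(s2$group, "ACLD")
  expect_equal(s2$acld_stage, "decompensated")
  # boundary: the cutoff itself is ACLD (closed on the ACLD side)
  expect_equal(classify_stage(list(fib4 = 1.75))$group, "ACLD")
  expect_equal(classify_stage(list(fib4 = 1.3))$fib4_category, "intermediate")
  expect_equal(classify_stage(list(fib4 = 2.67))$fib4_category, "intermediate")
  expect_equal(classify_stage(list(fib4 = 2.68))$fib4_category, "high")
  expect_equal(classify_stage(list(fib4 = NA))$group, "unclassifiable")
  expect_equal(classify_stage(list(fib4 = NA), cld = FALSE)$group, "control")
})

test_that("median and quartiles use linear interpolation", {
  expect_equal(unname(median_iqr(c(1, 2, 3, 4, 5))), c(3, 2, 4))
  expect_equal(unname(median_iqr(rep(7, 4))), c(7, 7, 7))
  expect_equal(unname(median_iqr(1:8)),
               unname(quantile(1:8, c(.5, .25, .75), type = 7)))
  expect_error(median_iqr(numeric(0)), class = "hepavol_empty_input")
})

test_that("Kruskal-Wallis H matches the rank-sum formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12) # hand-evaluated, no ties
  expect_equal(kw$df, 2)
  kw0 <- kruskal_wallis(list(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  # two-group case agrees with the Mann-Whitney normal approximation
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  p_kw <- kruskal_wallis(list(a, b))$p
  p_mwu <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE))$p.value
  expect_equal(p_kw, p_mwu, tolerance = 0.01)
})

test_that("Bonferroni correction clamps at 1 and stays monotone", {
  g <- list(a = c(1, 5, 3, 7), b = c(2, 8, 4, 9), c = c(1, 1, 2, 2))
  res <- pairwise_mwu_bonferroni(g)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_bonferroni <= 1))
  expect_true(all(res$p_bonferroni >= res$p_raw))
  expect_equal(res$p_bonferroni,
               pmin(1, res$p_raw * 3))
  # degenerate pair flagged NA
  res2 <- pairwise_mwu_bonferroni(list(a = 1:3, b = numeric(0)))
  expect_true(is.na(res2$p_bonferroni))
})

test_that("exact and normal-approximation Mann-Whitney p-values agree", {
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(8, 0.8)
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value      # oracle mode
    p_pkg <- hepavol:::mwu_p(a, b)                           # n <= 8: exact
    expect_identical(p_pkg, p_exact)
    p_norm <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE))$p.value
    expect_equal(p_pkg, p_norm, tolerance = 0.06)
  }
})

test_that("percent decreases reproduce median arithmetic to one decimal", {
  expect_identical(percent_decrease(3.9, 2.8), 28.2)
  expect_identical(percent_decrease(2.1, 1.0), 52.4)
  expect_identical(percent_decrease(5, 5), 0)
  expect_error(percent_decrease(0, 1), class = "hepavol_empty_input")
})

test_that("Spearman rho is exact on small examples and rank-invariant", {
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3))$rho, 0.5) # 1 - 12/24
  x <- c(0.3, 1.1, 2.2, 3.5, 7)
  expect_equal(spearman_rho(x, exp(x))$rho, 1.0)
  expect_equal(spearman_rho(x, -x^3)$rho, -1.0)
  # invariance under strictly monotone transforms
  set.seed(11)
  a <- rnorm(40); b <- a + rnorm(40)
  base <- spearman_rho(a, b)
  tra <- spearman_rho(exp(a), b^3 + 5 * b)
  expect_equal(base$rho, tra$rho)
  # cross-check against the standard implementation
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(base$rho, unname(ct$estimate))
  expect_equal(base$p, ct$p.value, tolerance = 0.02)
  expect_true(is.na(spearman_rho(c(1, NA), c(2, 3))$rho))
})

test_that("correlation maps are pairwise-complete over missing biomarkers", {
  co <- simulate_cohort(0, 20, 40, seed = 3)
  vvr <- data.frame(hvvr_pct = co$target_hvvr_pct,
                    pvvr_pct = co$target_pvvr_pct)
  vvr$tvvr_pct <- vvr$hvvr_pct + vvr$pvvr_pct
  m <- spearman_map(vvr, co[, c("platelets", "lsm_kpa", "hvpg_mmhg")])
  lsm_n <- m$n[m$vvr == "hvvr_pct" & m$biomarker == "lsm_kpa"]
  expect_lt(lsm_n, 60)
  expect_equal(m$n[m$vvr == "hvvr_pct" & m$biomarker == "platelets"], 60)
})

test_that("subgroup analyses partition CLD subjects and tolerate empties", {
  co <- simulate_cohort(5, 15, 30, seed = 9)
  vvr <- data.frame(hvvr_pct = co$target_hvvr_pct,
                    pvvr_pct = co$target_pvvr_pct)
  vvr$tvvr_pct <- vvr$hvvr_pct + vvr$pvvr_pct
  sub <- subgroup_analyses(co, vvr)
  expect_named(sub, c("stage", "fib4_category"))
  # an empty subgroup yields NA comparisons but the run continues
  co2 <- co[co$group != "ACLD", ]
  vvr2 <- vvr[co$group != "ACLD", ]
  sub2 <- subgroup_analyses(co2, vvr2)
  expect_true(is.na(sub2$stage$hvvr$median_iqr$dACLD["median"]))
})

test_that("the full report wires groups, tests and correlations together", {
  co <- simulate_cohort(12, 12, 24, seed = 21)
  vvr <- data.frame(hvvr_pct = co$target_hvvr_pct,
                    pvvr_pct = co$target_pvvr_pct)
  vvr$tvvr_pct <- vvr$hvvr_pct + vvr$pvvr_pct
  rep <- cohort_stats(co, vvr)
  expect_s3_class(rep, "cohort_stats_report")
  expect_named(rep$comparisons, c("tvvr", "hvvr", "pvvr"))
  expect_equal(nrow(rep$comparisons$hvvr$pairwise), 3)
  expect_true(all(rep$comparisons$hvvr$pairwise$p_bonferroni <= 1))
  expect_named(rep$spearman, c("cld", "non_acld", "acld"))
})
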