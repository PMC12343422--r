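test_that("clinical scores evaluate their published formulas", {
  # FIB-4 = age x AST / (PLT x sqrt(ALT)) = 2400 / (150 sqrt(30))
  p <- compute_scores(list(age = 60, ast = 40, alt = 30, platelets = 150))
  expect_equal(p$fib4, 2400 / (150 * sqrt(30)), tolerance = 1e-12)
  expect_equal(p$fib4, 2.92, tolerance = 0.002)
  # ALBI with 1 umol/L bilirubin (log10 term 0) and 40 g/L albumin
  p2 <- compute_scores(list(bilirubin = 1 / 17.1, albumin = 4.0))
  expect_equal(p2$albi, -3.4, tolerance = 1e-6)
  # MELD-Na floors at 6 for healthy labs
  p3 <- compute_scores(list(bilirubin = 0.5, creatinine = 0.8, inr = 1.0,
                            sodium = 140))
  expect_gte(p3$meld_na, 6)
  expect_lte(p3$meld_na, 40)
  # missing lab -> explicit NA marker; zero lab -> error
  expect_true(is.na(compute_scores(list(age = 60))$fib4))
  expect_error(compute_scores(list(age = 60, ast = 40, alt = 30,
                                   platelets = 0)),
               class = "hepavol_invalid_lab")
})

test_that("cohort simulation has the right size, layout and determinism", {
  co <- simulate_cohort(35, 44, 118, seed = 1)
  expect_equal(nrow(co), 197)
  expect_equal(unname(table(co$group)[c("control", "non-ACLD", "ACLD")]),
               c(35, 44, 118), ignore_attr = TRUE)
  # controls carry no laboratory panel, and HVPG exists only in ACLD
  expect_true(all(is.na(co$albumin[co$group == "control"])))
  expect_true(all(is.na(co$hvpg_mmhg[co$group != "ACLD"])))
  expect_true(all(co$decompensated[co$group != "ACLD"] %in% FALSE))
  # byte-identical CSV under the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(co, f1, row.names = FALSE)
  write.csv(simulate_cohort(35, 44, 118, seed = 1), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
  expect_equal(nrow(simulate_cohort(0, 0, 0, seed = 1)), 0)
  expect_error(simulate_subject("martian"), class = "hepavol_bad_group")
})

test_that("simulated marginals recover the calibrated group medians", {
  big <- hepavol:::simulate_group("ACLD", 10000, group_marginals(),
                                  copula_spearman_targets())
  expect_equal(median(big$platelets), 130.5, tolerance = 10 / 130.5)
  expect_equal(median(big$bilirubin), 1.0, tolerance = 0.10)
  expect_equal(median(big$hvvr), 1.0, tolerance = 0.10)
  nb <- hepavol:::simulate_group("non-ACLD", 10000, group_marginals(),
                                 copula_spearman_targets())
  expect_equal(median(nb$platelets), 295.5, tolerance = 0.10 * 295.5,
               ignore_attr = TRUE)
  expect_equal(median(nb$hvvr), 1.7, tolerance = 0.10)
  # availability subsetting mirrors the reported per-variable n
  expect_equal(mean(!is.na(big$lsm)), 51 / 118, tolerance = 0.15)
  expect_equal(mean(!is.na(big$hvpg)), 50 / 118, tolerance = 0.15)
})

test_that("an identity copula yields uncorrelated draws", {
  R0 <- copula_spearman_targets()
  R0[] <- diag(nrow(R0))
  big <- hepavol:::simulate_group("ACLD", 10000, group_marginals(), R0)
  expect_lt(abs(spearman_rho(big$hvvr, big$platelets)$rho), 0.05)
  expect_lt(abs(spearman_rho(big$hvvr, big$bilirubin)$rho), 0.05)
})

test_that("configured correlation signs are recovered in the draws", {
  big <- hepavol:::simulate_group("ACLD", 10000, group_marginals(),
                                  copula_spearman_targets())
  expect_lt(spearman_rho(big$hvvr, big$bilirubin)$rho, 0)
  expect_lt(spearman_rho(big$hvvr, big$lsm)$rho, 0)
  expect_lt(spearman_rho(big$hvvr, big$spleen_volume_cc)$rho, 0)
  expect_gt(spearman_rho(big$hvvr, big$platelets)$rho, 0)
  expect_gt(spearman_rho(big$hvvr, big$albumin)$rho, 0)
  # magnitudes near the configured targets
  expect_equal(spearman_rho(big$hvvr, big$platelets)$rho, 0.40,
               tolerance = 0.15)
})

test_that("per-subject phantom specs inherit the latent VVR targets", {
  co <- simulate_cohort(1, 1, 1, seed = 7)
  sp <- phantom_spec_for_subject(co[3, ], seed = 7)
  expect_s3_class(sp, "phantom_spec")
  expect_identical(sp$target_hvvr_pct, co$target_hvvr_pct[3])
  sp2 <- phantom_spec_for_subject(co[2, ], seed = 7)
  expect_false(identical(sp$seed, sp2$seed))
})
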