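test_that("EDT reports mm distance to nearest background voxel center", {
  m <- array(0L, c(5, 5, 5))
  m[3, 3, 3] <- 1L
  dm <- edt_diameter(m, c(1, 1, 1))
  expect_equal(dm$values[3, 3, 3], 1.0)
  expect_true(all(is.na(dm$values[m == 0L])))

  # one-voxel-thick slab: background adjacent only along the 3 mm axis
  s <- array(0L, c(7, 7, 3))
  s[, , 2] <- 1L
  ds <- edt_diameter(s, c(1, 1, 3))
  expect_equal(ds$values[4, 4, 2], 3.0)
})

test_that("EDT on a thick cylinder peaks near the radius on the centerline", {
  dims <- c(13, 13, 20)
  sp <- c(1, 1, 1)
  seg <- matrix(c(6.5, 6.5, 0, 6.5, 6.5, 20, 4), 1)
  cyl <- rasterize_tree(seg, dims, sp)
  dm <- edt_diameter(cyl, sp)
  expect_equal(max(dm$values, na.rm = TRUE), 4.0, tolerance = 0.5 / 4)
  bf <- brute_force_edt(cyl, sp)
  expect_equal(dm$values, bf, tolerance = 1e-10)
})

test_that("EDT matches the exhaustive oracle on anisotropic random grids", {
  set.seed(71)
  for (i in 1:8) {
    d <- sample(4:12, 3, replace = TRUE)
    sp <- sample(c(0.8, 1, 1.5, 2.5), 3, replace = TRUE)
    m <- array(rbinom(prod(d), 1, runif(1, 0.3, 0.8)), d)
    expect_equal(edt_diameter(m, sp)$values, brute_force_edt(m, sp),
                 tolerance = 1e-10)
  }
})

test_that("bin fractions follow the half-open 0-5 / 5-10 / >10 convention", {
  mk <- function(vals) {
    d <- array(1L, c(length(vals), 1, 1))
    dm <- structure(list(values = array(vals, dim(d)), spacing = c(1, 1, 1),
                         bin_edges = c(5, 10)), class = "diameter_map")
    dm
  }
  expect_equal(unname(bin_fractions(mk(c(2, 2, 2)))), c(1, 0, 0))
  expect_equal(unname(bin_fractions(mk(c(4, 6, 12)))), rep(1 / 3, 3))
  expect_equal(unname(bin_fractions(mk(5))), c(0, 1, 0))   # boundary -> middle
  expect_equal(unname(bin_fractions(mk(10))), c(0, 0, 1))
  expect_error(bin_fractions(edt_diameter(array(0L, c(4, 4, 4)))),
               class = "hepavol_empty_input")
})

test_that("Dice obeys its identities", {
  a <- array(0L, c(6, 6, 6)); a[2:4, 2:4, 2:4] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5, 5, 5] <- 1L
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, b), 0.0)
  expect_equal(dice(array(0L, c(3, 3, 3)), array(0L, c(3, 3, 3))), 1.0)
  x <- array(0L, c(4, 4, 1)); x[1:2, 1, 1] <- 1L
  y <- array(0L, c(4, 4, 1)); y[2:3, 1, 1] <- 1L
  expect_equal(dice(x, y), 0.5) # |A|=|B|=2, overlap 1
  expect_error(dice(a, array(0L, c(5, 5, 5))),
               class = "hepavol_shape_mismatch")
})

test_that("Dice is symmetric and label-permutation invariant", {
  set.seed(5)
  for (i in 1:20) {
    a <- array(rbinom(8^3, 1, 0.4), c(8, 8, 8))
    b <- array(rbinom(8^3, 1, 0.4), c(8, 8, 8))
    expect_identical(dice(a, b), dice(b, a))
    perm <- sample(8)
    expect_equal(dice(a[perm, , ], b[perm, , ]), dice(a, b))
  }
})

test_that("per-bin Dice partitions by ground-truth calibre", {
  tc <- two_calibre_masks()
  # perfect prediction: both defined bins at 1
  r <- dice_by_bin(tc$full, tc$full, tc$spacing)
  expect_equal(unname(r$by_bin[!is.na(r$by_bin)]),
               rep(1, sum(!is.na(r$by_bin))))
  expect_true(!is.na(r$by_bin["0-5mm"]) && !is.na(r$by_bin["5-10mm"]))
  # prediction missing the thin branch entirely: the small-calibre bin
  # degrades (binning is per voxel, so the trunk's surface shell still
  # contributes to it) while the thick-core bin stays perfect
  r2 <- dice_by_bin(tc$trunk_only, tc$full, tc$spacing)
  expect_lt(r2$by_bin["0-5mm"], r$by_bin["0-5mm"])
  expect_equal(unname(r2$by_bin["5-10mm"]), 1.0)
  # every thin-branch voxel is indeed a miss in the small bin
  dm <- edt_diameter(tc$full, tc$spacing)
  thin_bin <- !is.na(dm$values) & dm$values < 5
  expect_equal(sum(tc$trunk_only & tc$thin & thin_bin), 0)
  # empty prediction: all defined bins 0
  r3 <- dice_by_bin(array(0L, tc$dims), tc$full, tc$spacing)
  expect_true(all(r3$by_bin[!is.na(r3$by_bin)] == 0))
  # empty ground-truth bin reported NA, not an error
  expect_true(is.na(r$by_bin[">10mm"]))
})

test_that("organ volume is voxel count times voxel volume in cc", {
  m <- array(0L, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- 1L
  expect_equal(organ_volume(m, c(1, 1, 1)), 1.0)
  expect_equal(organ_volume(m, c(1, 1, 2)), 2.0)
  expect_equal(organ_volume(array(0L, c(4, 4, 4)), c(1, 1, 1)), 0.0)
})

test_that("VVRs follow the liver-normalised percent convention", {
  lab <- array(0L, c(20, 20, 20))
  lab[2:19, 2:19, 2:19] <- 3L
  n_liver <- sum(lab == 3L)
  lab[3:6, 3:6, 3:6] <- 2L
  lab[10:12, 10:12, 10:12] <- 1L
  v <- vessel_to_volume_ratios(label_volume(lab, c(1, 1, 1)))
  expect_equal(v$hvvr_pct, 100 * 64 / n_liver)
  expect_equal(v$pvvr_pct, 100 * 27 / n_liver)
  expect_identical(v$tvvr_pct, v$hvvr_pct + v$pvvr_pct)
  # no vessels -> all zero
  lab0 <- array(3L, c(5, 5, 5))
  v0 <- vessel_to_volume_ratios(lab0, c(1, 1, 1))
  expect_equal(c(v0$tvvr_pct, v0$hvvr_pct, v0$pvvr_pct), c(0, 0, 0))
  expect_error(vessel_to_volume_ratios(array(0L, c(4, 4, 4)), c(1, 1, 1)),
               class = "hepavol_empty_input")
})

test_that("VVRs are invariant under voxel-spacing rescaling", {
  set.seed(9)
  lab <- array(sample(c(0L, 1L, 2L, 3L), 6^3, TRUE, c(.3, .1, .1, .5)),
               c(6, 6, 6))
  v1 <- vessel_to_volume_ratios(lab, c(1, 1, 1))
  v2 <- vessel_to_volume_ratios(lab, c(2.5, 1.7, 3.1))
  expect_equal(v1$tvvr_pct, v2$tvvr_pct)
  expect_equal(v1$hvvr_pct, v2$hvvr_pct)
})

test_that("external liver masks clip stray vessel voxels with a warning", {
  lab <- array(0L, c(8, 8, 8))
  lab[2:6, 2:6, 2:6] <- 3L
  lab[3:4, 3:4, 3:4] <- 2L
  lab[8, 8, 8] <- 1L # outside the organ mask
  liver <- lab == 3L | lab == 2L
  expect_warning(v <- vessel_to_volume_ratios(lab, c(1, 1, 1), liver = liver),
                 "clipped")
  expect_equal(v$pvvr_pct, 0)
})
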