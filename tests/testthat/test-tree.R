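test_that("rasterization matches the per-voxel distance oracle", {
  set.seed(3)
  for (i in 1:5) {
    dims <- c(14, 12, 10)
    sp <- c(1, runif(1, 0.8, 2), runif(1, 1, 3))
    n <- sample(1:3, 1)
    segs <- cbind(matrix(runif(n * 6, 2, 9), n), runif(n, 0.3, 2.5))
    expect_identical(rasterize_tree(segs, dims, sp),
                     brute_force_rasterize(segs, dims, sp))
  }
})

test_that("thin segments below half-spacing still mark axis voxels", {
  seg <- matrix(c(1, 5.5, 5.5, 19, 5.5, 5.5, 0.2), 1) # radius << spacing/2
  r <- rasterize_tree(seg, c(20, 11, 11), c(1, 1, 1))
  expect_gt(sum(r), 10) # the crossed voxel column survives
})

test_that("an empty tree rasterizes to an all-background grid", {
  tr <- structure(list(segments = NULL, system = "portal",
                       root_point_mm = c(0, 0, 0)), class = "vessel_tree")
  expect_identical(rasterize_tree(tr, c(8, 8, 8), c(1, 1, 1)),
                   array(0L, c(8, 8, 8)))
})

test_that("tree growth hits its volume target within the 10% contract", {
  liver <- small_liver()
  sp <- c(2.5, 2.5, 3)
  lv <- sum(liver) * prod(sp)
  for (seed in c(2, 13, 27)) {
    for (frac in c(0.012, 0.021, 0.03)) {
      tr <- grow_vascular_tree(liver, sp, "portal", target_fraction = frac,
                               rng_seed = seed)
      got <- sum(rasterize_tree(tr, dim(liver), sp)) * prod(sp)
      expect_lt(abs(got - frac * lv) / (frac * lv), 0.10)
    }
  }
})

test_that("tree growth is deterministic and structurally valid", {
  liver <- small_liver()
  sp <- c(2.5, 2.5, 3)
  t1 <- grow_vascular_tree(liver, sp, "hepatic", 0.02, rng_seed = 5)
  t2 <- grow_vascular_tree(liver, sp, "hepatic", 0.02, rng_seed = 5)
  expect_identical(t1$segments, t2$segments)
  segs <- t1$segments
  expect_true(all(segs[, "radius_mm"] > 0))
  # children taper: radius never grows with depth along any lineage
  for (d in sort(unique(segs[, "depth"]))[-1])
    expect_lte(max(segs[segs[, "depth"] == d, "radius_mm"]),
               max(segs[segs[, "depth"] == d - 1, "radius_mm"]))
  # child segments start where a parent ends
  starts <- segs[segs[, "depth"] > 1, 1:3, drop = FALSE]
  ends <- segs[, 4:6, drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    gaps <- sqrt(rowSums(sweep(ends, 2, starts[i, ])^2))
    expect_lt(min(gaps), 1e-9)
  }
  # midpoints inside the mask
  mids <- (segs[, 1:3] + segs[, 4:6]) / 2
  idx <- floor(sweep(mids, 2, sp, `/`)) + 1
  for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), dim(liver)[k])
  expect_true(all(liver[idx]))
})

test_that("invalid geometry is rejected", {
  liver <- small_liver()
  sp <- c(2.5, 2.5, 3)
  expect_error(grow_vascular_tree(liver, sp, "portal", 0.02,
                                  root_point_mm = c(-50, -50, -50)),
               class = "hepavol_invalid_geometry")
  expect_error(grow_vascular_tree(liver, sp, "portal", 0.7),
               class = "hepavol_invalid_geometry")
  tr <- grow_vascular_tree(liver, sp, "portal", 0.02, rng_seed = 1)
  expect_error(rasterize_tree(tr, c(4, 4, 4), c(1, 1, 1)),
               class = "hepavol_invalid_geometry")
})
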