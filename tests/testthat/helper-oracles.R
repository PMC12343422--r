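# Independent brute-force oracles and small fixture builders.

# Exhaustive nearest-background Euclidean distance (mm) for every
# foreground voxel; O(n_fg * n_bg), for small grids only.
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  co <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                              z = seq_len(d[3])))
  pos <- sweep(co, 2, spacing, `*`)
  fg <- which(mask != 0)
  bg <- pos[mask[co] == 0, , drop = FALSE]
  out <- array(NA_real_, d)
  if (nrow(bg) == 0L) {
    out[fg] <- Inf
    return(out)
  }
  tb <- t(bg)
  out[fg] <- vapply(fg, function(i)
    sqrt(min(colSums((tb - pos[i, ])^2))), numeric(1))
  out
}

# Per-voxel distance-to-segment rasterisation oracle (same foreground rule
# as the implementation contract: inside radius, or the thin-vessel floor).
brute_force_rasterize <- function(segs, dims, spacing) {
  out <- array(0L, dims)
  hmin <- 0.5 * min(spacing)
  co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  pos <- sweep(co - 0.5, 2, spacing, `*`)
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1:3]; b <- segs[s, 4:6]; r <- segs[s, 7]
    u <- b - a
    len2 <- sum(u^2)
    rel <- sweep(pos, 2, a)
    tt <- if (len2 > 0) pmin(1, pmax(0, c(rel %*% u) / len2)) else 0
    dvec <- sqrt(rowSums((rel - outer(tt, u))^2))
    out[co[dvec <= r | dvec < hmin, , drop = FALSE]] <- 1L
  }
  out
}

# A small ellipsoidal liver mask for tree tests.
small_liver <- function(gs = c(32, 28, 20), sp = c(2.5, 2.5, 3)) {
  hepavol:::ellipsoid_mask(gs, sp, gs * sp * 0.5, gs * sp * 0.38)
}

# Two-calibre vessel phantom: thick trunk + thin branch, axis-aligned.
# `thin` holds the branch voxels outside the trunk, so trunk_only removes
# the branch without carving into the trunk at the junction.
two_calibre_masks <- function() {
  dims <- c(40, 24, 24)
  sp <- c(1, 1, 1)
  trunk <- matrix(c(2, 12, 12, 26, 12, 12, 6), 1)    # core EDT >= 5 mm
  branch <- matrix(c(26, 12, 12, 38, 12, 12, 2), 1)  # calibre ~2 mm
  full <- rasterize_tree(rbind(trunk, branch), dims, sp)
  thin <- rasterize_tree(branch, dims, sp) & !rasterize_tree(trunk, dims, sp)
  list(full = full, trunk_only = full & !thin, thin = thin,
       dims = dims, spacing = sp)
}
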