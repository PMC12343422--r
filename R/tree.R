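#' Grow a synthetic bifurcating vascular tree inside a liver mask
#'
#' Recursively bifurcates tube segments from a root on the mask boundary
#' (a hilum surrogate for the portal system, an inferior-vena-cava surrogate
#' for the hepatic system), tapering radii down the generations, and then
#' rescales all radii so that the rasterized tree occupies a target fraction
#' of the liver volume (within 10\% relative). The root trunk of the hepatic
#' tree stands in for the intrahepatic inferior vena cava and is part of the
#' hepatic label.
#'
#' @param liver_mask Logical/binary 3D array (or `image_volume`).
#' @param spacing_mm Voxel spacing in mm (ignored if `liver_mask` is a volume).
#' @param system `"portal"` or `"hepatic"`; sets root placement and initial
#'   growth direction.
#' @param target_fraction Desired rasterized tree volume as a fraction of the
#'   liver volume; must be in (0, 0.5).
#' @param branch_params Optional list overriding growth controls:
#'   `max_depth` (generations), `length_frac` (first-segment length as a
#'   fraction of the liver's longest extent), `length_taper`, `radius_taper`
#'   range, `angle_deg` range at bifurcations.
#' @param rng_seed Integer seed; identical seeds give identical trees.
#' @param root_point_mm Optional root override in mm; must lie inside the
#'   mask (else an invalid-geometry error).
#' @param measure_within_mask Logical; when `TRUE` the attained volume is
#'   measured on voxels inside the liver mask only (the convention phantom
#'   construction uses, since vessel labels are clipped to the liver).
#' @param avoid Optional binary array of voxels already claimed by another
#'   structure; those voxels are excluded from the attained-volume
#'   measurement (used so two overlapping systems still hit their targets
#'   after label-overlap resolution).
#' @return A `vessel_tree`: list with `segments` (matrix with columns
#'   x0,y0,z0,x1,y1,z1,radius_mm,depth), `system`, `root_point_mm`.
#' @export
grow_vascular_tree <- function(liver_mask, spacing_mm = NULL,
                               system = c("portal", "hepatic"),
                               target_fraction = 0.02,
                               branch_params = list(), rng_seed = 1L,
                               root_point_mm = NULL,
                               measure_within_mask = FALSE, avoid = NULL) {
  system <- match.arg(system)
  if (inherits(liver_mask, "image_volume")) {
    spacing_mm <- liver_mask$spacing
    liver_mask <- liver_mask$data
  }
  if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  mask <- liver_mask != 0
  if (!any(mask))
    stop_hepavol("hepavol_invalid_geometry", "liver mask is empty")
  if (!(target_fraction > 0 && target_fraction < 0.5))
    stop_hepavol("hepavol_invalid_geometry",
                 "target_fraction must be in (0, 0.5)")
  bp <- modifyList(list(max_depth = 6L, length_frac = 0.32,
                        length_taper = 0.78, radius_taper = c(0.65, 0.8),
                        angle_deg = c(25, 55), n_retries = 14L), branch_params)
  dims <- dim(mask)
  h <- as.numeric(spacing_mm)

  in_mask <- function(p) {
    i <- pmin(pmax(1L, as.integer(floor(p / h)) + 1L), dims)
    all(p >= 0) && all(p <= dims * h) && mask[i[1], i[2], i[3]]
  }

  idx <- which(mask, arr.ind = TRUE)
  centers <- sweep(idx - 0.5, 2, h, `*`)
  centroid <- colMeans(centers)
  extent <- max(apply(centers, 2, function(v) diff(range(v))))

  # Root: extreme mask point along the system axis (portal inferior,
  # hepatic superior along the third axis).
  if (is.null(root_point_mm)) {
    k <- if (system == "portal") which.min(centers[, 3]) else which.max(centers[, 3])
    root <- centers[k, ]
  } else {
    root <- as.numeric(root_point_mm)
    if (!in_mask(root))
      stop_hepavol("hepavol_invalid_geometry",
                   "root point lies outside the liver mask")
  }

  rot_about <- function(v, axis, theta) { # Rodrigues rotation
    axis <- axis / sqrt(sum(axis^2))
    v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
      axis * sum(axis * v) * (1 - cos(theta))
  }
  pracma_cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  rand_perp <- function(u) {
    repeat {
      w <- rnorm(3)
      w <- w - sum(w * u) * u
      n <- sqrt(sum(w^2))
      if (n > 1e-8) return(w / n)
    }
  }

  segs <- with_seed(rng_seed, {
    acc <- list()
    grow <- function(p, u, len, r, depth) {
      if (depth > bp$max_depth || r <= 0) return()
      q <- NULL
      for (try in seq_len(bp$n_retries)) {
        cand <- p + len * u
        mid <- (p + cand) / 2
        if (in_mask(mid) && in_mask(cand)) { q <- cand; break }
        # steer toward the centroid and shorten slightly
        pull <- centroid - p
        pull <- pull / max(sqrt(sum(pull^2)), 1e-9)
        u <- u + 0.45 * pull + 0.25 * rnorm(3)
        u <- u / sqrt(sum(u^2))
        len <- len * 0.9
      }
      if (is.null(q)) return()
      acc[[length(acc) + 1L]] <<- c(p, q, r, depth)
      if (depth == bp$max_depth) return()
      theta <- runif(2, bp$angle_deg[1], bp$angle_deg[2]) * pi / 180
      ax <- rand_perp(u)
      for (s in c(1, -1)) {
        u_child <- rot_about(u, ax, s * theta[(3 - s) / 2])
        r_child <- r * runif(1, bp$radius_taper[1], bp$radius_taper[2])
        grow(q, u_child, len * bp$length_taper, r_child, depth + 1L)
      }
    }
    u0 <- centroid - root
    u0 <- u0 / max(sqrt(sum(u0^2)), 1e-9)
    grow(root, u0, bp$length_frac * extent, 1.0, 1L)
    if (length(acc) == 0) NULL else do.call(rbind, acc)
  })
  if (is.null(segs))
    stop_hepavol("hepavol_shortfall", "tree growth produced no segments")
  colnames(segs) <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius_mm", "depth")

  # Scale radii so the rasterized volume hits the target fraction. Thin
  # branches never drop below the half-spacing rasterization floor, so a
  # full-depth tree has a minimum attainable volume; when the target sits
  # below that floor, deeper generations are pruned until it is reachable.
  liver_vol_mm3 <- sum(mask) * prod(h)
  target_mm3 <- target_fraction * liver_vol_mm3
  keep <- if (measure_within_mask) mask else TRUE
  if (!is.null(avoid)) keep <- keep & !(as_volume_data(avoid) != 0)
  tree <- NULL
  for (depth_cap in seq(bp$max_depth, 1L)) {
    sub <- segs[segs[, "depth"] <= depth_cap, , drop = FALSE]
    seg_len <- sqrt(rowSums((sub[, 4:6, drop = FALSE] -
                             sub[, 1:3, drop = FALSE])^2))
    unit_vol <- sum(pi * sub[, "radius_mm"]^2 * seg_len)
    s <- sqrt(target_mm3 / unit_vol)
    for (it in 1:6) {
      cand <- sub
      cand[, "radius_mm"] <- sub[, "radius_mm"] * s
      tr <- structure(list(segments = cand, system = system,
                           root_point_mm = root), class = "vessel_tree")
      ras <- rasterize_tree(tr, dims, h)
      got <- sum(ras != 0 & keep) * prod(h)
      # tolerance: 6% relative, floored at ~a voxel (volume is quantized)
      tol <- max(0.06 * target_mm3, 1.25 * prod(h))
      if (got > 0 && abs(got - target_mm3) <= tol) {
        tree <- tr
        break
      }
      if (got == 0) s <- s * 1.5 else s <- s * sqrt(target_mm3 / got)
    }
    if (!is.null(tree)) break
  }
  if (is.null(tree))
    stop_hepavol("hepavol_shortfall",
                 "could not reach target fraction %.4g within tolerance",
                 target_fraction)
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %s system, %d segments, root (%.1f, %.1f, %.1f) mm\n",
              x$system, nrow(x$segments), x$root_point_mm[1],
              x$root_point_mm[2], x$root_point_mm[3]))
  invisible(x)
}

#' Rasterize a vessel tree onto a voxel grid
#'
#' A voxel is foreground iff its center lies within the segment radius of any
#' segment axis (distances in mm, honouring anisotropic spacing), or within
#' half the minimum spacing of the axis — the thin-vessel guarantee that
#' keeps sub-voxel branches from being silently dropped.
#'
#' @param tree A `vessel_tree` (or a segment matrix with the same columns).
#' @param grid_shape Integer length-3 voxel counts.
#' @param spacing_mm Voxel spacing in mm.
#' @return Integer 0/1 array of shape `grid_shape`. An empty tree gives an
#'   all-background grid.
#' @export
rasterize_tree <- function(tree, grid_shape, spacing_mm) {
  segs <- if (inherits(tree, "vessel_tree")) tree$segments else tree
  grid_shape <- as.integer(grid_shape)
  if (is.null(segs) || nrow(segs) == 0L)
    return(array(0L, grid_shape))
  lim <- grid_shape * spacing_mm
  pts <- rbind(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE])
  if (any(pts < -1e-9) || any(sweep(pts, 2, lim) > 1e-9))
    stop_hepavol("hepavol_invalid_geometry",
                 "tree segments extend beyond the grid")
  .rasterize_segments(segs[, 1:7, drop = FALSE], grid_shape,
                      as.numeric(spacing_mm))
}
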