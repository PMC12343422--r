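#' Specification for a synthetic liver phantom
#'
#' Describes the geometry, vessel-volume targets and intensity model of one
#' phantom: an ellipsoidal liver and spleen, a portal and a hepatic vascular
#' tree grown to prescribed vessel-to-volume fractions, portal-venous-phase
#' intensity ordering (vessels > parenchyma > background), optional additive
#' Gaussian noise and a low-frequency multiplicative bias field emulating
#' receive-coil shading.
#'
#' @param grid_shape Voxels per axis (all >= 16).
#' @param spacing_mm Voxel size in mm per axis (all > 0).
#' @param liver_axes_mm,spleen_axes_mm Ellipsoid semi-axes in mm.
#' @param target_hvvr_pct,target_pvvr_pct Desired hepatic / portal vessel
#'   volume as percent of liver volume; their sum must be in (0, 50).
#' @param noise_sigma Additive Gaussian intensity noise SD (image units).
#' @param bias_field_amplitude Amplitude of the multiplicative shading field
#'   (0.1 = +/-10 percent).
#' @param seed RNG seed; phantoms are deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 48, 32),
                         spacing_mm = c(2.5, 2.5, 3.0),
                         liver_axes_mm = c(58, 42, 34),
                         spleen_axes_mm = c(17, 15, 13),
                         target_hvvr_pct = 2.1,
                         target_pvvr_pct = 1.7,
                         noise_sigma = 0.04,
                         bias_field_amplitude = 0.1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (any(grid_shape < 16L))
    stop_hepavol("hepavol_invalid_geometry", "all grid_shape must be >= 16")
  if (any(spacing_mm <= 0))
    stop_hepavol("hepavol_invalid_geometry", "all spacing_mm must be > 0")
  tot <- target_hvvr_pct + target_pvvr_pct
  if (!(tot > 0 && tot < 50))
    stop_hepavol("hepavol_invalid_geometry",
                 "target_hvvr_pct + target_pvvr_pct must be in (0, 50)")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 liver_axes_mm = as.numeric(liver_axes_mm),
                 spleen_axes_mm = as.numeric(spleen_axes_mm),
                 target_hvvr_pct = target_hvvr_pct,
                 target_pvvr_pct = target_pvvr_pct,
                 noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid mask on the voxel grid: center and semi-axes in mm.
ellipsoid_mask <- function(grid_shape, spacing_mm, center_mm, axes_mm) {
  cx <- (seq_len(grid_shape[1]) - 0.5) * spacing_mm[1]
  cy <- (seq_len(grid_shape[2]) - 0.5) * spacing_mm[2]
  cz <- (seq_len(grid_shape[3]) - 0.5) * spacing_mm[3]
  dx2 <- ((cx - center_mm[1]) / axes_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / axes_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / axes_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Smooth multiplicative shading: product of low-order cosine basis functions
# rescaled to [-1, 1], one factor per axis.
bias_field <- function(grid_shape, spacing_mm, phase = c(0, 0, 0)) {
  f <- function(n, ph) cos(pi * (seq_len(n) - 0.5) / n + ph)
  bx <- f(grid_shape[1], phase[1])
  by <- f(grid_shape[2], phase[2])
  bz <- f(grid_shape[3], phase[3])
  b <- outer(outer(bx, by), bz)
  b / max(abs(b))
}

#' Build a synthetic liver phantom
#'
#' Generates an intensity volume, a multi-class label map (0 background,
#' 1 portal vein, 2 hepatic veins, 3 liver parenchyma, 4 spleen) and the
#' ground-truth vessel-to-volume ratios. The ground truth is computed from
#' the emitted label map by [vessel_to_volume_ratios()] — not from the
#' analytic tree — so ground truth and downstream metrics share a single
#' convention. Intensity plateaus before noise/bias: background 0, liver
#' parenchyma 0.5, spleen 0.65, vessels 1.0.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (`image_volume`), `labels` (`label_volume`),
#'   `ground_truth_vvr` (`vvr_result`), and the two `vessel_tree`s.
#' @export
make_liver_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  h <- spec$spacing_mm
  ext <- gs * h
  liver_c <- ext * c(0.44, 0.48, 0.52)
  liver <- ellipsoid_mask(gs, h, liver_c, spec$liver_axes_mm)
  if (!any(liver))
    stop_hepavol("hepavol_invalid_geometry", "liver ellipsoid misses the grid")
  spleen_c <- ext * c(0.88, 0.78, 0.42)
  spleen <- ellipsoid_mask(gs, h, spleen_c, spec$spleen_axes_mm) & !liver

  portal_tree <- grow_vascular_tree(liver, h, "portal",
                                    target_fraction = spec$target_pvvr_pct / 100,
                                    rng_seed = child_seed(spec$seed, "portal"),
                                    measure_within_mask = TRUE)
  portal <- rasterize_tree(portal_tree, gs, h) != 0L & liver
  hepatic_tree <- grow_vascular_tree(liver, h, "hepatic",
                                     target_fraction = spec$target_hvvr_pct / 100,
                                     rng_seed = child_seed(spec$seed, "hepatic"),
                                     measure_within_mask = TRUE,
                                     avoid = portal)
  hepatic <- rasterize_tree(hepatic_tree, gs, h) != 0L & liver

  lab <- array(0L, gs)
  lab[liver] <- 3L
  lab[spleen] <- 4L
  lab[hepatic] <- 2L
  lab[portal] <- 1L  # overlap resolved in favour of the portal system

  img <- array(0, gs)
  img[lab == 3L] <- 0.5
  img[lab == 4L] <- 0.65
  img[lab == 1L | lab == 2L] <- 1.0
  if (spec$bias_field_amplitude > 0 || spec$noise_sigma > 0) {
    img <- with_seed(child_seed(spec$seed, "intensity"), {
      if (spec$bias_field_amplitude > 0) {
        ph <- runif(3, 0, pi)
        img <- img * (1 + spec$bias_field_amplitude * bias_field(gs, h, ph))
      }
      if (spec$noise_sigma > 0)
        img <- img + array(rnorm(length(img), sd = spec$noise_sigma), gs)
      img
    })
  }

  labels <- label_volume(lab, h)
  gt <- vessel_to_volume_ratios(labels)
  # construction contract: 10% relative, floored at ~2 voxels of volume
  # (coarse grids quantize small vessel systems)
  vox_pct <- 100 * 2.5 / sum(liver)
  for (nm in c("hvvr", "pvvr")) {
    target <- spec[[paste0("target_", nm, "_pct")]]
    got <- gt[[paste0(nm, "_pct")]]
    if (abs(got - target) > max(0.10 * target, vox_pct))
      stop_hepavol("hepavol_shortfall",
                   "%s %.3f%% misses target %.3f%% by more than 10%%",
                   toupper(nm), got, target)
  }
  list(image = image_volume(img, h), labels = labels, ground_truth_vvr = gt,
       portal_tree = portal_tree, hepatic_tree = hepatic_tree)
}
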