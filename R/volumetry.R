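#' Per-voxel vessel calibre via the Euclidean distance transform
#'
#' For every foreground voxel, the exact Euclidean distance in millimetres to
#' the nearest background voxel center, honouring anisotropic spacing. The
#' EDT value itself is reported as the vessel "diameter", following the
#' field's convention for calibre stratification (geometrically it is a
#' radius-like quantity; see the methods vignette).
#'
#' @param mask Binary array (or `image_volume`) marking vessel foreground.
#' @param spacing_mm Voxel spacing in mm (ignored if `mask` is a volume).
#' @return Object of class `diameter_map`: list with `values` (numeric array,
#'   `NA` outside the foreground), `spacing`, and `bin_edges` (mm).
#' @examples
#' m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
#' dm <- edt_diameter(m, c(1, 1, 1))
#' dm$values[3, 3, 3]  # 1.0: nearest background center is one voxel away
#' @export
edt_diameter <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "image_volume")) {
    spacing_mm <- mask$spacing
    mask <- mask$data
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  mi <- array(as.integer(mask != 0), dim = dim(mask))
  d <- .edt_mm(mi, dim(mi), as.numeric(spacing_mm))
  d[mi == 0L] <- NA_real_
  structure(list(values = d, spacing = as.numeric(spacing_mm),
                 bin_edges = c(5, 10)),
            class = "diameter_map")
}

#' Diameter-bin voxel fractions
#'
#' Fractions of vessel foreground falling in the calibre bins
#' `[0, 5)`, `[5, 10)` and `[10, Inf)` mm (half-open, left-closed; a value of
#' exactly 5 mm falls in the middle bin).
#'
#' @param dmap A `diameter_map` from [edt_diameter()].
#' @return Named numeric vector of length 3 summing to 1.
#' @export
bin_fractions <- function(dmap) {
  stopifnot(inherits(dmap, "diameter_map"))
  v <- dmap$values[!is.na(dmap$values)]
  if (length(v) == 0L)
    stop_hepavol("hepavol_empty_input", "diameter map has no foreground voxels")
  e <- dmap$bin_edges
  counts <- c(sum(v < e[1]), sum(v >= e[1] & v < e[2]), sum(v >= e[2]))
  setNames(counts / length(v), c("0-5mm", "5-10mm", ">10mm"))
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b Binary arrays (or volumes) on congruent grids.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_volume_data(mask_a) != 0
  b <- as_volume_data(mask_b) != 0
  if (!identical(dim(a), dim(b)))
    stop_hepavol("hepavol_shape_mismatch", "masks have different shapes")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Dice stratified by ground-truth vessel calibre
#'
#' Partitions the ground-truth foreground into calibre bins via
#' [edt_diameter()] computed on the ground truth, and reports Dice between
#' prediction and ground truth restricted to each bin region. The bin
#' region is the bin mask dilated by one voxel (so boundary predictions are
#' absorbed) minus the ground-truth voxels of the other bins (so a perfect
#' prediction scores exactly 1 in every bin). Bins with no ground-truth
#' voxels are reported as `NA` and excluded from averages.
#'
#' Binning is per voxel on the raw EDT value, so a thick vessel contributes
#' its surface shell to the smallest bin; per-bin Dice therefore mixes
#' calibre classes at structure boundaries (see the methods vignette).
#'
#' @param pred_mask,gt_mask Binary arrays (or volumes) on congruent grids.
#' @param spacing Voxel spacing in mm.
#' @return A `dice_report`: list with `overall`, `by_bin` (named numeric,
#'   `NA` for undefined bins) and `bin_fractions` of the ground truth.
#' @export
dice_by_bin <- function(pred_mask, gt_mask, spacing = c(1, 1, 1)) {
  if (inherits(gt_mask, "image_volume")) spacing <- gt_mask$spacing
  p <- as_volume_data(pred_mask) != 0
  g <- as_volume_data(gt_mask) != 0
  if (!identical(dim(p), dim(g)))
    stop_hepavol("hepavol_shape_mismatch", "masks have different shapes")
  overall <- dice(p, g)
  if (!any(g)) {
    return(structure(list(overall = overall,
                          by_bin = setNames(rep(NA_real_, 3),
                                            c("0-5mm", "5-10mm", ">10mm")),
                          bin_fractions = NULL),
                     class = "dice_report"))
  }
  dm <- edt_diameter(g, spacing)
  e <- dm$bin_edges
  v <- dm$values
  bins <- list(`0-5mm` = !is.na(v) & v < e[1],
               `5-10mm` = !is.na(v) & v >= e[1] & v < e[2],
               `>10mm` = !is.na(v) & v >= e[2])
  by_bin <- vapply(bins, function(bm) {
    if (!any(bm)) return(NA_real_)
    region <- .dilate_box3(array(as.integer(bm), dim(bm)), dim(bm)) != 0L
    region <- region & !(g & !bm)
    dice(p & region, g & bm)
  }, numeric(1))
  structure(list(overall = overall, by_bin = by_bin,
                 bin_fractions = bin_fractions(dm)),
            class = "dice_report")
}

#' Organ volume in cc from a binary mask
#'
#' @param mask Binary array (or volume).
#' @param spacing_mm Voxel spacing in mm.
#' @return Volume in cubic centimetres (1 cc = 1000 mm^3).
#' @export
organ_volume <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "image_volume")) {
    spacing_mm <- mask$spacing
    mask <- mask$data
  }
  if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  sum(mask != 0) * prod(spacing_mm) / 1000
}

#' Vessel-to-volume ratios from a label map
#'
#' Vessel volumes normalised to total liver volume, expressed in percent:
#' HVVR = 100 V_hepatic / V_liver, PVVR = 100 V_portal / V_liver, and
#' TVVR = HVVR + PVVR. The liver denominator includes the vessel voxels
#' (vessels are part of the liver mask). Vessel voxels outside the liver
#' trigger a warning and are clipped to the liver.
#'
#' @param labels A `label_volume` (0/1/2/3/4 convention) or integer array.
#' @param spacing_mm Voxel spacing in mm (ignored if `labels` is a volume).
#' @param liver An optional explicit liver organ mask. By default the liver
#'   is derived from the label map itself (labels 1, 2, 3), in which case
#'   vessels are inside the liver by construction. When an external mask is
#'   supplied, vessel voxels outside it are clipped with a warning.
#' @return A `vvr_result`: list with `tvvr_pct`, `hvvr_pct`, `pvvr_pct`,
#'   component volumes in cc and `liver_volume_cc`.
#' @examples
#' lab <- array(3L, c(10, 10, 10))
#' lab[1:2, 1:2, 1:2] <- 1L  # a little portal blob
#' vessel_to_volume_ratios(label_volume(lab, c(1, 1, 1)))
#' @export
vessel_to_volume_ratios <- function(labels, spacing_mm = NULL, liver = NULL) {
  if (inherits(labels, "image_volume")) {
    spacing_mm <- labels$spacing
    lab <- labels$data
  } else {
    lab <- labels
    if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  }
  portal <- lab == 1L
  hepatic <- lab == 2L
  liver <- if (is.null(liver)) lab == 1L | lab == 2L | lab == 3L
           else as_volume_data(liver) != 0
  n_liver <- sum(liver)
  if (n_liver == 0)
    stop_hepavol("hepavol_empty_input", "liver mask is empty")
  n_out <- sum((portal | hepatic) & !liver)
  if (n_out > 0) {
    warning(sprintf("%d vessel voxels outside liver; clipped", n_out))
    portal <- portal & liver
    hepatic <- hepatic & liver
  }
  vx <- prod(spacing_mm) / 1000
  hvvr <- 100 * sum(hepatic) / n_liver
  pvvr <- 100 * sum(portal) / n_liver
  structure(list(tvvr_pct = hvvr + pvvr, hvvr_pct = hvvr, pvvr_pct = pvvr,
                 hepatic_volume_cc = sum(hepatic) * vx,
                 portal_volume_cc = sum(portal) * vx,
                 liver_volume_cc = n_liver * vx),
            class = "vvr_result")
}

#' @export
print.vvr_result <- function(x, ...) {
  cat(sprintf("TVVR %.2f%%  HVVR %.2f%%  PVVR %.2f%%  (liver %.1f cc)\n",
              x$tvvr_pct, x$hvvr_pct, x$pvvr_pct, x$liver_volume_cc))
  invisible(x)
}
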