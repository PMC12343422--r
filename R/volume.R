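#' Image and label volume containers
#'
#' An `image_volume` is a 3D numeric array plus a per-axis voxel spacing in
#' millimetres; a `label_volume` is the integer-valued counterpart holding a
#' per-voxel class map. These are the units every pipeline stage consumes.
#' Voxel `(i, j, k)` (1-based) has its physical center at
#' `(i - 0.5, j - 0.5, k - 0.5) * spacing` mm.
#'
#' Label conventions for the multi-class map: 0 background, 1 intrahepatic
#' portal vein, 2 hepatic veins (including the intrahepatic inferior vena
#' cava), 3 liver parenchyma, 4 spleen. Vessel labels lie inside the liver,
#' so the liver mask is `label %in% c(1, 2, 3)`.
#'
#' @param data 3D numeric (or integer, for labels) array.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @return An object of class `image_volume` or `label_volume`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 2))
#' voxel_volume_cc(v)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_hepavol("hepavol_invalid_geometry", "spacing must be 3 positive numbers")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @rdname image_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  storage.mode(data) <- "integer"
  v <- image_volume(data, spacing)
  class(v) <- c("label_volume", "image_volume")
  v
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Physical volume of one voxel, in cc
#' @param vol An `image_volume` or `label_volume`.
#' @return Voxel volume in cubic centimetres.
#' @export
voxel_volume_cc <- function(vol) prod(vol$spacing) / 1000

# Internal coercion: accept a plain array + spacing or a container.
as_volume_data <- function(x) {
  if (inherits(x, "image_volume")) x$data else x
}

#' Masks derived from a multi-class label map
#'
#' @param labels A `label_volume` with the 0/1/2/3/4 convention.
#' @return A logical array.
#' @export
liver_mask <- function(labels) {
  d <- as_volume_data(labels)
  d == 1L | d == 2L | d == 3L
}

#' @rdname liver_mask
#' @export
portal_mask <- function(labels) as_volume_data(labels) == 1L

#' @rdname liver_mask
#' @export
hepatic_mask <- function(labels) as_volume_data(labels) == 2L

#' @rdname liver_mask
#' @export
spleen_mask <- function(labels) as_volume_data(labels) == 4L

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that carry the voxel spacing in the
#' header. Label maps are written as integer volumes.
#'
#' @param vol An `image_volume` or `label_volume`.
#' @param path File path, conventionally ending in `.nii.gz`.
#' @return `read_volume` returns an `image_volume` (or `label_volume` when
#'   `labels = TRUE`); `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$data)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @param labels Logical; read as a `label_volume`?
#' @export
read_volume <- function(path, labels = FALSE) {
  im <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(im)[seq_len(3)]
  arr <- array(as.vector(im), dim = dim(im)[seq_len(3)])
  if (labels) label_volume(round(arr), spacing = sp)
  else image_volume(arr, spacing = sp)
}
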