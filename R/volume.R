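#' 3D image volume
#'
#' Lightweight container for a scalar 3D MR volume: a numeric array plus the
#' physical voxel spacing (mm) and the world position of the first voxel
#' centre (mm). All geometric feature computations in the package work in
#' millimetres derived from `spacing`.
#'
#' @param data 3D numeric array of voxel intensities (arbitrary units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world coordinates of voxel (1,1,1) in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  if (any(!is.finite(data))) stop("image data must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' Binary segmentation mask
#'
#' Binary region-of-interest mask on the same grid as its paired
#' [image_volume()]; here the labyrinth segmentation.
#'
#' @param data 3D array with values 0/1 (logical accepted).
#' @param spacing,origin as in [image_volume()]; must match the paired image.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "seg_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing, digits = 3), collapse = "x")))
  invisible(x)
}

stopifnot_paired <- function(img, mask) {
  if (!identical(dim(img$data), dim(mask$data)))
    stop("image and mask grids differ")
  if (max(abs(img$spacing - mask$spacing)) > 1e-9)
    stop("image and mask spacing differ")
}

#' Write / read NIfTI volumes
#'
#' Thin wrappers around RNifti keeping spacing metadata intact. Images are
#' stored as 32-bit float, masks as 8-bit unsigned integer.
#'
#' @param vol an `image_volume` or `seg_mask`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `write_nifti` returns `path` invisibly; `read_nifti_volume` /
#'   `read_nifti_mask` return the corresponding container.
#' @export
write_nifti <- function(vol, path) {
  datatype <- if (inherits(vol, "seg_mask")) "uint8" else "float"
  nii <- RNifti::asNifti(structure(vol$data, pixdim = vol$spacing),
                         datatype = datatype)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  image_volume(array(as.numeric(nii), dim(nii)[1:3]),
               spacing = RNifti::pixdim(nii)[1:3])
}

#' @rdname write_nifti
#' @export
read_nifti_mask <- function(path) {
  nii <- RNifti::readNifti(path)
  seg_mask(array(as.integer(as.vector(nii) > 0.5), dim(nii)[1:3]),
           spacing = RNifti::pixdim(nii)[1:3])
}
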