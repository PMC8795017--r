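#' Isotropic resampling with cubic-spline interpolation
#'
#' Resamples an image/mask pair onto an axis-aligned isotropic grid of
#' voxel length `target_mm` (default 0.5 mm). Interpolation is a separable
#' tensor-product cubic spline applied axis by axis; since spline
#' interpolation is linear in the data, each axis is resampled by a
#' precomputed interpolation matrix built from [stats::spline()] responses
#' to unit impulses. The mask is interpolated as a float field and
#' re-binarized at 0.5. The output origin equals the input origin and the
#' world extent is preserved to within one voxel.
#'
#' @param img an [image_volume()].
#' @param mask the paired [seg_mask()].
#' @param target_mm isotropic target voxel length in mm.
#' @return list with resampled `img` and `mask`.
#' @export
resample_isotropic <- function(img, mask, target_mm = 0.5) {
  stopifnot_paired(img, mask)
  if (target_mm <= 0) stop("target_mm must be positive")
  d <- dim(img$data)
  idata <- img$data
  mdata <- mask$data + 0  # float copy for spline interpolation
  for (ax in 1:3) {
    sp_in <- img$spacing[ax]
    if (abs(sp_in - target_mm) < 1e-12) next
    n_in <- d[ax]
    x_in <- (seq_len(n_in) - 1) * sp_in
    n_out <- floor((n_in - 1) * sp_in / target_mm) + 1
    x_out <- (seq_len(n_out) - 1) * target_mm
    A <- spline_matrix(x_in, x_out)
    idata <- apply_along_axis(idata, ax, A)
    mdata <- apply_along_axis(mdata, ax, A)
    d[ax] <- n_out
  }
  mbin <- array(as.integer(mdata >= 0.5), d)
  if (sum(mbin) == 0) stop("ROI lost in resampling")
  list(img = image_volume(idata, spacing = rep(target_mm, 3),
                          origin = img$origin),
       mask = seg_mask(mbin, spacing = rep(target_mm, 3),
                       origin = mask$origin))
}

# Cubic-spline interpolation matrix: row i gives the weights producing the
# spline value at x_out[i] from samples at x_in. Exact for the data because
# interpolating splines are linear operators of the samples.
spline_matrix <- function(x_in, x_out) {
  n <- length(x_in)
  A <- matrix(0, length(x_out), n)
  if (n == 1) {
    A[, 1] <- 1
    return(A)
  }
  e <- numeric(n)
  for (j in seq_len(n)) {
    e[] <- 0
    e[j] <- 1
    A[, j] <- stats::spline(x_in, e, xout = x_out, method = "fmm")$y
  }
  A
}

#' Z-score intensity normalization
#'
#' Linearly transforms intensities so the volume has mean 0 and population
#' SD 1, removing per-scan brightness/contrast (affine intensity)
#' differences between centers. `scope = "roi"` computes the statistics
#' over the mask only (the transform is still applied to the whole volume).
#'
#' @param img an [image_volume()].
#' @param mask optional [seg_mask()], required for `scope = "roi"`.
#' @param scope `"volume"` (default) or `"roi"`.
#' @return The normalized [image_volume()].
#' @export
znormalize <- function(img, mask = NULL, scope = c("volume", "roi")) {
  scope <- match.arg(scope)
  vals <- if (scope == "roi") {
    if (is.null(mask)) stop("scope = 'roi' requires a mask")
    img$data[mask$data > 0]
  } else as.vector(img$data)
  m <- mean(vals)
  s <- sd_pop(vals)
  if (!is.finite(s) || s < 1e-12)
    stop("zero-variance image cannot be Z-score normalized")
  image_volume((img$data - m) / s, spacing = img$spacing, origin = img$origin)
}

#' Fixed-bin-width gray-level discretization
#'
#' Assigns each ROI voxel the integer gray level
#' `floor((x - min_ROI) / bin_width) + 1`, with bin edges anchored at the
#' ROI minimum; the maximum-intensity voxel gets level
#' `Ng = floor((max - min) / bin_width) + 1`. Voxels outside the ROI are 0.
#'
#' @param img an [image_volume()] (normally Z-score normalized).
#' @param mask the paired [seg_mask()] (nonempty).
#' @param bin_width fixed bin width in (normalized) intensity units.
#' @return A `discretized_roi`: list with `labels` (integer array, 0 outside
#'   ROI), `n_levels`, `bin_width`, `roi_min`.
#' @export
discretize <- function(img, mask, bin_width = 0.5) {
  stopifnot_paired(img, mask)
  if (bin_width <= 0) stop("bin_width must be positive")
  inside <- mask$data > 0
  if (!any(inside)) stop("cannot discretize an empty ROI")
  vals <- img$data[inside]
  lv <- discretize_values(vals, bin_width)
  labels <- array(0L, dim(img$data))
  labels[inside] <- lv$labels
  structure(list(labels = labels, n_levels = lv$n_levels,
                 bin_width = bin_width, roi_min = lv$roi_min),
            class = "discretized_roi")
}

# Core fixed-bin-width rule on a numeric vector.
discretize_values <- function(vals, bin_width) {
  lo <- min(vals)
  ng <- as.integer(floor((max(vals) - lo) / bin_width)) + 1L
  labs <- as.integer(floor((vals - lo) / bin_width)) + 1L
  labs[labs > ng] <- ng  # guards the exact-maximum edge case
  list(labels = labs, n_levels = ng, roi_min = lo)
}
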