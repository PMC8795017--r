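# First-order intensity statistics of the ROI. Histogram-based entries
# (entropy, uniformity) use the fixed-bin-width discretization; everything
# else uses the raw ROI intensities. Percentiles use linear interpolation
# between order statistics (quantile type 7).

firstorder_feature_names <- function() {
  paste0("Stats_", c(
    "min", "max", "range", "mean", "median", "p10", "p90", "variance",
    "skewness", "kurtosis", "energy", "rms", "mad", "iqr", "entropy",
    "uniformity", "rmad", "total_energy"))
}

#' First-order statistical features
#'
#' @param img an [image_volume()] (intensities the statistics are taken of).
#' @param mask the paired [seg_mask()] (nonempty).
#' @param disc the [discretize()] output for the same pair, used for the
#'   histogram-based entropy and uniformity.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(img, mask, disc) {
  x <- img$data[mask$data > 0]
  if (length(x) == 0) stop("cannot compute first-order features of empty ROI")
  firstorder_from_values(x, disc$labels[mask$data > 0], disc$n_levels,
                         voxel_volume = prod(img$spacing))
}

firstorder_from_values <- function(x, labels, n_levels, voxel_volume) {
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)  # population variance
  q <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE,
                       type = 7)
  skew <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((x - m)^4) / v^2 else 0
  energy <- sum(x^2)
  p <- tabulate(labels, nbins = n_levels) / n
  pz <- p[p > 0]
  entropy <- -sum(pz * log2(pz))
  uniformity <- sum(p^2)
  in_robust <- x >= q[1] & x <= q[5]
  rmad <- if (any(in_robust)) mean(abs(x[in_robust] - mean(x[in_robust])))
          else 0
  out <- c(min(x), max(x), max(x) - min(x), m, q[3], q[1], q[5], v, skew,
           kurt, energy, sqrt(energy / n), mean(abs(x - m)), q[4] - q[2],
           entropy, uniformity, rmad, energy * voxel_volume)
  names(out) <- firstorder_feature_names()
  out
}
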