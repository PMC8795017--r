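# Coiflet-1 analysis filters (orthonormal, 6 taps; low-pass sums to sqrt(2)).
coif1_filters <- function() {
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
          0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  list(lo = lo, hi = hi)
}

# Single-level undecimated circular convolution along one axis:
# y[i] = sum_k h[k] x[(i - k + 4) mod n], matching the common stationary
# wavelet transform alignment with periodic boundary handling.
swt_conv_axis <- function(arr, axis, h) {
  n <- dim(arr)[axis]
  if (n < length(h))
    stop(sprintf("axis %d (length %d) shorter than wavelet filter (%d taps)",
                 axis, n, length(h)))
  out <- array(0, dim(arr))
  for (k in seq_along(h)) {
    out <- out + h[k] * roll_axis(arr, axis, k - 4L)
  }
  out
}

#' Single-level stationary 3D wavelet decomposition
#'
#' Applies a one-level undecimated (stationary) 3D wavelet transform with
#' the Coiflet-1 kernel, producing the eight separable sub-bands LLL..HHH
#' (letter order = axes 1..3; L = low-pass, H = high-pass). Because the
#' transform is undecimated, every sub-band lives on the input grid, so the
#' original segmentation mask applies unchanged. Boundary handling is
#' periodic.
#'
#' @param img an [image_volume()] (normally resampled and normalized).
#' @return Named list of eight [image_volume()] sub-bands
#'   (`LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`, `HHL`, `HHH`).
#' @export
wavelet_decompose <- function(img) {
  f <- coif1_filters()
  bands <- list(img$data)
  names(bands) <- ""
  for (ax in 1:3) {
    nxt <- list()
    for (b in seq_along(bands)) {
      nxt[[paste0(names(bands)[b], "L")]] <- swt_conv_axis(bands[[b]], ax, f$lo)
      nxt[[paste0(names(bands)[b], "H")]] <- swt_conv_axis(bands[[b]], ax, f$hi)
    }
    bands <- nxt
  }
  order <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(order, function(nm) {
    image_volume(bands[[nm]], spacing = img$spacing, origin = img$origin)
  })
  names(out) <- order
  out
}
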