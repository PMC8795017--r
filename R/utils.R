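# Internal helpers shared across modules.

# Derive a stream of reproducible child seeds from one master seed without
# disturbing the caller's RNG state more than once. Keeps every seed in
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Population standard deviation (divides by n, not n - 1).
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Apply a linear operator (matrix) along one axis of a 3D array.
apply_along_axis <- function(arr, axis, A) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- A %*% m
  d2 <- d
  d2[axis] <- nrow(A)
  out <- array(out, dim = d2[perm])
  aperm(out, order(perm))
}

# Circularly shift a 3D array by `by` voxels along `axis` (positive = values
# move toward higher indices).
roll_axis <- function(arr, axis, by) {
  n <- dim(arr)[axis]
  by <- ((by %% n) + n) %% n
  if (by == 0) return(arr)
  idx <- c((n - by + 1L):n, 1L:(n - by))
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
gaussian_smooth3 <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    out <- arr * k[r + 1]
    for (j in 1:r) {
      out <- out + k[r + 1 + j] * roll_axis(arr, ax, j) +
        k[r + 1 - j] * roll_axis(arr, ax, -j)
    }
    arr <- out
  }
  arr
}

# L2 norm of the separable 3D Gaussian kernel used above (so smoothed white
# noise can be rescaled back to unit variance deterministically).
gaussian_kernel_l2 <- function(sigma) {
  sigma <- rep(sigma, length.out = 3)
  prod(vapply(sigma, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    sqrt(sum(k^2))
  }, numeric(1)))
}

# Bounding box (per-axis index ranges) of positive voxels.
mask_bbox <- function(maskdata) {
  idx <- which(maskdata > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box")
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

# Crop image+mask arrays to the mask bounding box expanded by `margin`
# voxels (clamped at the grid edge).
crop_to_mask <- function(img, mask, margin = 4L) {
  bb <- mask_bbox(mask$data)
  d <- dim(mask$data)
  lo <- pmax(bb$lo - margin, 1L)
  hi <- pmin(bb$hi + margin, d)
  sl <- lapply(1:3, function(a) lo[a]:hi[a])
  list(
    img = image_volume(img$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                       spacing = img$spacing,
                       origin = img$origin + (lo - 1) * img$spacing),
    mask = seg_mask(mask$data[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                    spacing = mask$spacing,
                    origin = mask$origin + (lo - 1) * mask$spacing)
  )
}
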