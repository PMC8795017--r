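# Brute-force oracles, deliberately naive: plain voxel loops, independent of
# the vectorized implementations they validate.

oracle_dirs13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric normalized GLCM by explicit pair enumeration.
oracle_glcm <- function(labels, offset, ng) {
  d <- dim(labels)
  C <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- labels[i, j, k]
    if (a == 0) next
    q <- c(i, j, k) + offset
    if (!in_grid(q, d)) next
    b <- labels[q[1], q[2], q[3]]
    if (b == 0) next
    C[a, b] <- C[a, b] + 1
  }
  C <- C + t(C)
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# Run-length matrix by walking every grid line in the given direction.
oracle_glrlm <- function(labels, dir, ng) {
  d <- dim(labels)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c(i, j, k)
    # only start walking from line origins (no predecessor inside the grid)
    if (in_grid(p - dir, d)) next
    lab_prev <- 0L
    len <- 0L
    while (in_grid(p, d)) {
      lab <- labels[p[1], p[2], p[3]]
      if (lab != 0 && lab == lab_prev) {
        len <- len + 1L
      } else {
        if (lab_prev != 0L) runs[[length(runs) + 1L]] <- c(lab_prev, len)
        lab_prev <- lab
        len <- if (lab != 0) 1L else 0L
      }
      p <- p + dir
    }
    if (lab_prev != 0L) runs[[length(runs) + 1L]] <- c(lab_prev, len)
  }
  if (length(runs) == 0) return(matrix(0, ng, 1))
  rl <- do.call(rbind, runs)
  P <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) {
    P[rl[r, 1], rl[r, 2]] <- P[rl[r, 1], rl[r, 2]] + 1
  }
  P
}

# Size-zone matrix by breadth-first flood fill with 26-connectivity.
oracle_glszm <- function(labels, ng) {
  d <- dim(labels)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (labels[i, j, k] == 0 || seen[i, j, k]) next
    lab <- labels[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (q in seq_len(nrow(offs))) {
        nb <- p + offs[q, ]
        if (!in_grid(nb, d)) next
        if (seen[nb[1], nb[2], nb[3]]) next
        if (labels[nb[1], nb[2], nb[3]] != lab) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nb
      }
    }
    zones[[length(zones) + 1L]] <- c(lab, size)
  }
  zs <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) {
    P[zs[r, 1], zs[r, 2]] <- P[zs[r, 1], zs[r, 2]] + 1
  }
  P
}

# Dependence counts by explicit neighbor loops (dependence size includes the
# centre voxel, alpha = 0).
oracle_gldm <- function(labels, ng) {
  d <- dim(labels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  deps <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    lab <- labels[i, j, k]
    if (lab == 0) next
    dep <- 1L
    for (q in seq_len(nrow(offs))) {
      nb <- c(i, j, k) + offs[q, ]
      if (!in_grid(nb, d)) next
      if (labels[nb[1], nb[2], nb[3]] == lab) dep <- dep + 1L
    }
    deps[[length(deps) + 1L]] <- c(lab, dep)
  }
  dd <- do.call(rbind, deps)
  P <- matrix(0, ng, max(dd[, 2]))
  for (r in seq_len(nrow(dd))) {
    P[dd[r, 1], dd[r, 2]] <- P[dd[r, 1], dd[r, 2]] + 1
  }
  P
}

# Direct (non-separable) circular 3D convolution with the outer product of
# three 1D kernels, alignment y[i] = sum_k h[k] x[i - k + 4].
oracle_swt3 <- function(x, h1, h2, h3) {
  d <- dim(x)
  y <- array(0, d)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(h1)) for (b in seq_along(h2)) for (cc in seq_along(h3)) {
      acc <- acc + h1[a] * h2[b] * h3[cc] *
        x[wrap(i - a + 4, d[1]), wrap(j - b + 4, d[2]), wrap(k - cc + 4, d[3])]
    }
    y[i, j, k] <- acc
  }
  y
}

# Random small label grid with a random ROI (0 = outside).
random_label_grid <- function(dims, ng, p_roi = 0.7) {
  arr <- array(0L, dims)
  roi <- stats::runif(prod(dims)) < p_roi
  arr[roi] <- sample.int(ng, sum(roi), replace = TRUE)
  arr
}

disc_from_labels <- function(labels, ng) {
  structure(list(labels = labels, n_levels = ng, bin_width = 1, roi_min = 0),
            class = "discretized_roi")
}

# Digital ball mask helper.
ball_mask <- function(r_vox, spacing = c(0.5, 0.5, 0.5), pad = 3L) {
  gs <- rep(2L * r_vox + 2L * pad + 1L, 3)
  ctr <- (gs - 1) / 2
  x <- (0:(gs[1] - 1)) - ctr[1]
  X <- array(rep(x, gs[2] * gs[3]), gs)
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  seg_mask(array(as.integer(X^2 + Y^2 + Z^2 <= r_vox^2), gs),
           spacing = spacing)
}

# Small fast phantom parameters for unit tests (reduced anatomy on a small
# grid so one extraction takes well under a second).
tiny_phantom <- function(...) {
  phantom_params(grid_shape = c(32L, 32L, 32L), spacing = c(0.5, 0.5, 0.5),
                 vestibule_radii = c(2.6, 2.2, 1.9), canal_radius = 3.6,
                 canal_tube_radius = 0.7, canal_offset_mm = 1.4, ...)
}
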