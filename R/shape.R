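# 3D shape descriptors of a binary mask, computed in mm from the voxel
# spacing. Surface quantities come from a triangulated isosurface of the
# (lightly Gaussian-smoothed, anti-aliased) mask extracted by marching
# tetrahedra at iso-level 0.5; smoothing removes voxelization staircase bias
# so the surface area of a digital ball converges to the analytic value.

shape_feature_names <- function() {
  paste0("Shape_", c(
    "mesh_volume", "voxel_volume", "surface_area", "surface_volume_ratio",
    "sphericity", "compactness1", "compactness2", "spherical_disproportion",
    "max_3d_diameter", "max_2d_diameter_slice", "max_2d_diameter_row",
    "max_2d_diameter_column", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness",
    "bbox_len_x", "bbox_len_y", "bbox_len_z"))
}

#' Shape features of a segmentation mask
#'
#' Computes 20 3D morphology descriptors (volumes, mesh surface area and
#' derived sphericity/compactness measures, maximum diameters, inertia axis
#' lengths, bounding-box lengths) in mm-based units.
#'
#' @param mask a nonempty [seg_mask()].
#' @return Named numeric vector of 20 features.
#' @export
shape_features <- function(mask) {
  m <- mask$data
  sp <- mask$spacing
  nvox <- sum(m)
  if (nvox == 0) stop("cannot compute shape features of an empty mask")
  voxvol <- prod(sp)

  mesh <- mask_isosurface(m, sp)
  A <- mesh$area
  V <- mesh$volume
  if (V <= 0) V <- nvox * voxvol  # tiny-mask fallback (degenerate mesh)
  if (A <= 0) A <- .Machine$double.eps

  r_equiv <- (3 * V / (4 * pi))^(1 / 3)
  sphericity <- (36 * pi * V^2)^(1 / 3) / A
  comp1 <- V / (sqrt(pi) * A^(3 / 2))
  comp2 <- 36 * pi * V^2 / A^3
  sph_disp <- A / (4 * pi * r_equiv^2)

  idx <- which(m > 0, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, `*`)

  bidx <- boundary_voxels(m)
  bpts <- sweep(bidx - 1, 2, sp, `*`)
  d3 <- max_pairwise_distance(bpts)
  d2 <- max_2d_diameters(bidx, sp)

  if (nvox > 1) {
    cc <- sweep(coords, 2, colMeans(coords))
    cov <- crossprod(cc) / nvox  # population covariance of voxel centres
    ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  bb <- mask_bbox(m)
  bbox_len <- (bb$hi - bb$lo + 1) * sp

  out <- c(V, nvox * voxvol, A, A / V, sphericity, comp1, comp2, sph_disp,
           d3, d2[3], d2[1], d2[2], major, minor, least, elong, flat,
           bbox_len[1], bbox_len[2], bbox_len[3])
  names(out) <- shape_feature_names()
  out
}

# Anti-aliased triangulated isosurface of a binary mask via marching
# tetrahedra; returns total triangle area and enclosed (divergence-theorem)
# volume, both in mm units.
mask_isosurface <- function(m, sp, sigma_vox = 0.9, iso = 0.5) {
  # Pad so the surface closes even when the mask touches the grid edge;
  # padding must cover the smoothing kernel support.
  pad <- as.integer(ceiling(3 * sigma_vox) + 1)
  d <- dim(m)
  F <- array(0, d + 2L * pad)
  F[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  F <- gaussian_smooth3(F, sigma_vox)

  dd <- dim(F)
  n1 <- dd[1]; n2 <- dd[2]; n3 <- dd[3]

  # Candidate cells: straddle the iso-level across their 8 corners.
  sub <- function(i, j, k) F[i, j, k, drop = FALSE]
  i1 <- 1:(n1 - 1); i2 <- 2:n1
  j1 <- 1:(n2 - 1); j2 <- 2:n2
  k1 <- 1:(n3 - 1); k2 <- 2:n3
  corner <- list(sub(i1, j1, k1), sub(i2, j1, k1), sub(i2, j2, k1),
                 sub(i1, j2, k1), sub(i1, j1, k2), sub(i2, j1, k2),
                 sub(i2, j2, k2), sub(i1, j2, k2))
  cmin <- Reduce(pmin, corner)
  cmax <- Reduce(pmax, corner)
  cells <- which(cmin < iso & cmax >= iso)
  if (length(cells) == 0) return(list(area = 0, volume = 0, vertices = NULL))

  cidx <- arrayInd(cells, dd - 1L)
  vals <- vapply(corner, function(a) a[cells], numeric(length(cells)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)

  # Corner offsets (unit cube, matching the `corner` list above).
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
              c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  # Six-tetrahedron decomposition around the 1-7 main diagonal.
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

  base <- sweep(cidx - 1, 2, sp, `*`)  # cell origin in mm (voxel centres)
  spm <- matrix(sp, nrow = length(cells), ncol = 3, byrow = TRUE)

  area_tot <- 0
  vol_tot <- 0
  vert_acc <- list()

  interp <- function(pa, pb, va, vb) {
    t <- (iso - va) / (vb - va)
    pa + (pb - pa) * t
  }

  emit <- function(p1, p2, p3, pin) {
    # Orient so the normal points away from the inside reference point,
    # accumulate area and signed (outward) volume.
    e1 <- p2 - p1
    e2 <- p3 - p1
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    cen <- (p1 + p2 + p3) / 3
    ref <- cen - pin
    flip <- (nx * ref[, 1] + ny * ref[, 2] + nz * ref[, 3]) < 0
    s <- ifelse(flip, -1, 1)
    nx <- s * nx; ny <- s * ny; nz <- s * nz
    area_tot <<- area_tot + sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
    # Divergence theorem with outward normals: V = sum x-flux.
    vol_tot <<- vol_tot + sum(cen[, 1] * nx) / 2
    vert_acc[[length(vert_acc) + 1L]] <<- rbind(p1, p2, p3)
  }

  for (t in seq_len(nrow(tets))) {
    tv <- tets[t, ]
    v <- vals[, tv, drop = FALSE]
    inside <- v >= iso
    ncase <- rowSums(inside)
    active <- which(ncase > 0 & ncase < 4)
    if (length(active) == 0) next
    bact <- base[active, , drop = FALSE]
    sact <- spm[active, , drop = FALSE]
    va <- v[active, , drop = FALSE]
    ia <- inside[active, , drop = FALSE]
    nc <- ncase[active]
    # position of local tet corner q (1..4), per active cell, vectorized:
    # base + cube-corner offset * spacing
    pos_of <- function(qs, rows) {
      bact[rows, , drop = FALSE] +
        sact[rows, , drop = FALSE] * co[tv[qs], , drop = FALSE]
    }
    val_of <- function(qs, rows) va[cbind(rows, qs)]

    # Single corner in/out: one triangle between that corner and the rest.
    for (lone_in in c(TRUE, FALSE)) {
      sel <- which(if (lone_in) nc == 1 else nc == 3)
      if (length(sel) == 0) next
      iam <- if (lone_in) ia[sel, , drop = FALSE] else !ia[sel, , drop = FALSE]
      lone <- max.col(iam * 1, ties.method = "first")  # one TRUE per row
      others <- matrix(0L, length(sel), 3)
      for (q in 1:4) {
        rows <- lone == q
        if (any(rows)) others[rows, ] <- matrix(rep(setdiff(1:4, q),
                                                    each = sum(rows)),
                                                sum(rows), 3)
      }
      pl <- pos_of(lone, sel)
      vl <- val_of(lone, sel)
      tri <- vector("list", 3)
      for (q in 1:3) {
        tri[[q]] <- interp(pl, pos_of(others[, q], sel),
                           vl, val_of(others[, q], sel))
      }
      pin <- if (lone_in) pl else {
        (pos_of(others[, 1], sel) + pos_of(others[, 2], sel) +
           pos_of(others[, 3], sel)) / 3
      }
      emit(tri[[1]], tri[[2]], tri[[3]], pin)
    }

    # Two in / two out: quad split into two triangles.
    sel <- which(nc == 2)
    if (length(sel) > 0) {
      iam <- ia[sel, , drop = FALSE]
      ord <- t(apply(iam, 1, order, decreasing = TRUE))  # 2 in then 2 out
      inA <- ord[, 1]; inB <- ord[, 2]; outC <- ord[, 3]; outD <- ord[, 4]
      pA <- pos_of(inA, sel); vA <- val_of(inA, sel)
      pB <- pos_of(inB, sel); vB <- val_of(inB, sel)
      pC <- pos_of(outC, sel); vC <- val_of(outC, sel)
      pD <- pos_of(outD, sel); vD <- val_of(outD, sel)
      eAC <- interp(pA, pC, vA, vC)
      eAD <- interp(pA, pD, vA, vD)
      eBC <- interp(pB, pC, vB, vC)
      eBD <- interp(pB, pD, vB, vD)
      pin <- (pA + pB) / 2
      emit(eAC, eAD, eBD, pin)
      emit(eAC, eBD, eBC, pin)
    }
  }

  verts <- unique(do.call(rbind, vert_acc))
  # Shift vertices back to the unpadded frame.
  verts <- sweep(verts, 2, pad * sp)
  list(area = area_tot, volume = abs(vol_tot), vertices = verts)
}

# Indices of boundary voxels (6-connectivity): mask voxels with at least
# one face-neighbor outside the mask. Extreme points of the mask (in 3D and
# within any slice) always lie on this set.
boundary_voxels <- function(m) {
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core == 1L & nb < 6L, arr.ind = TRUE)
}

# Exact maximum pairwise Euclidean distance, chunked to bound memory.
max_pairwise_distance <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  if (is.null(n) || n < 2) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    cross <- pts[s:e, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[s:e], rep(1, n)) + outer(rep(1, e - s + 1L), sq) - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# Maximum in-plane diameters for planes normal to each axis, from the
# boundary voxel set (in-plane extremes are 3D boundary voxels).
max_2d_diameters <- function(bidx, sp) {
  vapply(1:3, function(ax) {
    keep <- setdiff(1:3, ax)
    best <- 0
    for (grp in split(seq_len(nrow(bidx)), bidx[, ax])) {
      if (length(grp) < 2) next
      pts <- sweep(bidx[grp, keep, drop = FALSE] - 1, 2, sp[keep], `*`)
      best <- max(best, max_pairwise_distance(pts))
    }
    best
  }, numeric(1))
}
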