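# Gray-level texture matrices and their scalar features, computed from a
# discretized ROI (integer label array, 0 outside the ROI). All matrix
# construction is vectorized over ROI voxels; tests cross-check it against
# brute-force voxel-pair / run / zone enumeration.

# The 13 unique 3D directions at Chebyshev distance 1 (one per +/- pair).
texture_directions <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

roi_voxel_index <- function(labels) {
  lin <- which(labels > 0L)
  list(lin = lin, coord = arrayInd(lin, dim(labels)), lab = labels[lin])
}

# Shared neighborhood precomputation: for each ROI voxel, the ROI-node index
# of its neighbor along each of the 13 canonical directions and their 13
# negatives (0 = neighbor outside grid or outside ROI), plus neighbor labels.
texture_neighborhood <- function(labels, roi) {
  d <- dim(labels)
  n <- length(roi$lin)
  node_of <- array(0L, d)
  node_of[roi$lin] <- seq_len(n)
  dirs <- texture_directions()
  nd <- nrow(dirs)
  fwd <- matrix(0L, n, nd)
  for (q in seq_len(nd)) {
    nb <- sweep(roi$coord, 2, dirs[q, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (any(ok)) {
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
        (nb[ok, 3] - 1L) * d[1] * d[2]
      fwd[ok, q] <- node_of[lin]
    }
  }
  # reverse directions by scattering: u is v's -d neighbor iff v is u's +d
  bwd <- matrix(0L, n, nd)
  for (q in seq_len(nd)) {
    has <- fwd[, q] > 0L
    bwd[fwd[has, q], q] <- which(has)
  }
  nodes26 <- cbind(fwd, bwd)
  labs26 <- matrix(0L, n, 2L * nd)
  pos <- nodes26 > 0L
  labs26[pos] <- roi$lab[nodes26[pos]]
  list(fwd_nodes = fwd, nodes26 = nodes26, labs26 = labs26)
}

## ---------------------------------------------------------------- GLCM ----

# Symmetric normalized GLCM for one direction; NULL when no pairs exist.
# `nb` = neighbor labels of the ROI voxels for that direction.
glcm_matrix_from_nb <- function(lab, nb, ng) {
  keep <- nb > 0L
  if (!any(keep)) return(NULL)
  a <- lab[keep]
  b <- nb[keep]
  cnt <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
  C <- matrix(cnt, ng, ng, byrow = TRUE)
  C <- C + t(C)  # symmetrization = counting both pair orders
  C / sum(C)
}

glcm_feature_names <- function() {
  paste0("GLCM_", c(
    "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity",
    "joint_energy", "joint_entropy", "imc1", "imc2", "idm", "idmn", "id",
    "idn", "inverse_variance", "max_probability", "sum_average",
    "sum_entropy", "sum_variance", "sum_squares", "mcc"))
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)  # == mu_y by symmetry
  sig2 <- sum((seq_len(ng) - mu)^2 * px)

  # diagonal (|i-j|) and cross-diagonal (i+j) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))

  plog <- function(q) {
    qz <- q[q > 0]
    -sum(qz * log2(qz))
  }
  hxy <- plog(p)
  hx <- plog(px)
  pxpy <- px %o% px
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- plog(pxpy)

  da <- sum(k_diff * p_diff)
  sa <- sum(k_sum * p_sum)

  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  present <- px > 0
  mcc <- if (sum(present) > 1) {
    # Q_ij = sum_k p(i,k) p(j,k) / (px_i px_k), over present levels only
    M <- p[present, present, drop = FALSE] / px[present]
    evq <- sort(Re(eigen(M %*% M, only.values = TRUE)$values),
                decreasing = TRUE)
    sqrt(min(max(evq[2], 0), 1))
  } else 1

  offdiag <- abs(i - j) > 0
  c(sum(i * j * p),
    mu,
    sum((i + j - 2 * mu)^4 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    plog(p_diff),
    sum((k_diff - da)^2 * p_diff),
    sum(abs(i - j) * p),
    sum(p^2),
    hxy,
    imc1,
    imc2,
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + ((i - j) / ng)^2)),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + abs(i - j) / ng)),
    if (any(offdiag)) sum(p[offdiag] / (i - j)[offdiag]^2) else 0,
    max(p),
    sa,
    plog(p_sum),
    sum((k_sum - sa)^2 * p_sum),
    sum((i - mu)^2 * p),
    mcc)
}

#' Gray-level co-occurrence features
#'
#' Builds the symmetric GLCM at Chebyshev distance 1 for each of the 13
#' unique 3D directions and averages the 26 scalar features over directions
#' (directions with no valid voxel pair are skipped).
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 26 features.
#' @export
glcm_features <- function(disc) {
  roi <- roi_voxel_index(disc$labels)
  nbh <- texture_neighborhood(disc$labels, roi)
  glcm_features_impl(roi$lab, nbh$labs26[, 1:13, drop = FALSE],
                     disc$n_levels)
}

glcm_features_impl <- function(lab, nbm, ng) {
  acc <- NULL
  nd <- 0
  for (q in seq_len(ncol(nbm))) {
    p <- glcm_matrix_from_nb(lab, nbm[, q], ng)
    if (is.null(p)) next
    f <- glcm_features_one(p)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) acc <- glcm_features_one(matrix(1, 1, 1))
  else acc <- acc / nd
  names(acc) <- glcm_feature_names()
  acc
}

## --------------------------------------------------------------- GLRLM ----

# Run-length matrix (ng x max_len counts) for one direction: sort ROI
# voxels by (line id, position along line) and split at label changes or
# positional gaps.
glrlm_matrix <- function(labels, roi, dirvec, ng) {
  d <- dim(labels)
  co <- roi$coord
  tback <- rep(.Machine$integer.max, nrow(co))
  for (a in 1:3) {
    if (dirvec[a] == 1L) tback <- pmin(tback, co[, a] - 1L)
    else if (dirvec[a] == -1L) tback <- pmin(tback, d[a] - co[, a])
  }
  anchor <- co - tback %o% as.integer(dirvec)
  lineid <- (anchor[, 1] - 1) + (anchor[, 2] - 1) * d[1] +
    (anchor[, 3] - 1) * d[1] * d[2]
  ord <- order(lineid, tback)
  lid <- lineid[ord]
  pos <- tback[ord]
  lab <- roi$lab[ord]
  n <- length(lab)
  newrun <- c(TRUE, lid[-1] != lid[-n] | pos[-1] != pos[-n] + 1L |
                lab[-1] != lab[-n])
  runid <- cumsum(newrun)
  runlen <- tabulate(runid)
  runlab <- lab[newrun]
  maxlen <- max(runlen)
  cnt <- tabulate((runlab - 1L) * maxlen + runlen, nbins = ng * maxlen)
  matrix(cnt, ng, maxlen, byrow = TRUE)
}

szm_style_features <- function(P, n_roi) {
  # Shared feature set of the run-length / size-zone / dependence families:
  # rows = gray level i, columns = size s.
  ns <- sum(P)
  ng <- nrow(P)
  smax <- ncol(P)
  i <- matrix(seq_len(ng), ng, smax)
  s <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  pr <- P / ns
  ri <- rowSums(P)
  rs <- colSums(P)
  mu_i <- sum(i * pr)
  mu_s <- sum(s * pr)
  przero <- pr[pr > 0]
  c(sre = sum(P / s^2) / ns,
    lre = sum(P * s^2) / ns,
    gln = sum(ri^2) / ns,
    glnn = sum(ri^2) / ns^2,
    rln = sum(rs^2) / ns,
    rlnn = sum(rs^2) / ns^2,
    rp = ns / n_roi,
    glv = sum(pr * (i - mu_i)^2),
    rv = sum(pr * (s - mu_s)^2),
    re = -sum(przero * log2(przero)),
    lgre = sum(P / i^2) / ns,
    hgre = sum(P * i^2) / ns,
    srlge = sum(P / (i^2 * s^2)) / ns,
    srhge = sum(P * i^2 / s^2) / ns,
    lrlge = sum(P * s^2 / i^2) / ns,
    lrhge = sum(P * i^2 * s^2) / ns)
}

glrlm_feature_names <- function() {
  paste0("GLRLM_", c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                     "rv", "re", "lgre", "hgre", "srlge", "srhge", "lrlge",
                     "lrhge"))
}

#' Gray-level run-length features
#'
#' Run-length matrices over the 13 unique 3D directions; the 16 features
#' are averaged over directions.
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc) {
  roi <- roi_voxel_index(disc$labels)
  ng <- disc$n_levels
  dirs <- texture_directions()
  acc <- 0
  for (q in seq_len(nrow(dirs))) {
    P <- glrlm_matrix(disc$labels, roi, dirs[q, ], ng)
    acc <- acc + szm_style_features(P, length(roi$lin))
  }
  acc <- acc / nrow(dirs)
  names(acc) <- glrlm_feature_names()
  acc
}

## --------------------------------------------------------------- GLSZM ----

# Size-zone matrix: connected components (26-connectivity) of equal-label
# ROI voxels, via an igraph components decomposition.
glszm_matrix_from_nbh <- function(lab, nbh, ng) {
  n <- length(lab)
  fwd <- nbh$fwd_nodes
  edges <- list()
  for (q in seq_len(ncol(fwd))) {
    keep <- fwd[, q] > 0L & nbh$labs26[, q] == lab
    if (!any(keep)) next
    edges[[length(edges) + 1L]] <- cbind(which(keep), fwd[keep, q])
  }
  if (length(edges) > 0) {
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(n)]
  } else comp <- seq_len(n)
  zsize <- tabulate(comp)
  # gray level of each zone (constant within a zone by construction)
  zlab <- integer(max(comp))
  zlab[comp] <- lab
  smax <- max(zsize)
  cnt <- tabulate((zlab - 1L) * smax + zsize, nbins = ng * smax)
  matrix(cnt, ng, smax, byrow = TRUE)
}

glszm_feature_names <- function() {
  paste0("GLSZM_", c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
                     "zv", "ze", "lgze", "hgze", "salge", "sahge", "lalge",
                     "lahge"))
}

#' Gray-level size-zone features
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(disc) {
  roi <- roi_voxel_index(disc$labels)
  nbh <- texture_neighborhood(disc$labels, roi)
  P <- glszm_matrix_from_nbh(roi$lab, nbh, disc$n_levels)
  out <- szm_style_features(P, length(roi$lin))
  names(out) <- glszm_feature_names()
  out
}

## ---------------------------------------------------------------- GLDM ----

# Dependence matrix: for each ROI voxel, the dependence size is 1 (the
# voxel itself) plus the number of its 26-neighbors inside the ROI with
# identical gray level (alpha = 0).
gldm_matrix_from_nbh <- function(lab, nbh, ng) {
  dep <- 1L + rowSums(nbh$labs26 == lab & nbh$nodes26 > 0L)
  dmax <- max(dep)
  cnt <- tabulate((lab - 1L) * dmax + dep, nbins = ng * dmax)
  matrix(cnt, ng, dmax, byrow = TRUE)
}

gldm_feature_names <- function() {
  paste0("GLDM_", c("sde", "lde", "gln", "dn", "dnn", "glv", "dv"))
}

#' Gray-level dependence features
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 7 features.
#' @export
gldm_features <- function(disc) {
  roi <- roi_voxel_index(disc$labels)
  nbh <- texture_neighborhood(disc$labels, roi)
  P <- gldm_matrix_from_nbh(roi$lab, nbh, disc$n_levels)
  f <- szm_style_features(P, length(roi$lin))
  out <- c(f["sre"], f["lre"], f["gln"], f["rln"], f["rlnn"], f["glv"],
           f["rv"])
  names(out) <- gldm_feature_names()
  out
}

## --------------------------------------------------------------- NGTDM ----

ngtdm_feature_names <- function() {
  paste0("NGTDM_", c("coarseness", "contrast", "busyness", "complexity",
                     "strength"))
}

#' Neighborhood gray-tone difference features
#'
#' Uses the 26-neighborhood average gray level; only voxels with at least
#' one ROI neighbor enter the statistics. Degenerate cases follow the usual
#' epsilon conventions: coarseness is capped at 1e6 for a constant ROI and
#' busyness/strength are 0 when their denominators vanish.
#'
#' @param disc a [discretize()] result.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc) {
  roi <- roi_voxel_index(disc$labels)
  nbh <- texture_neighborhood(disc$labels, roi)
  ngtdm_features_impl(roi$lab, nbh, disc$n_levels)
}

ngtdm_features_impl <- function(roilab, nbh, ng) {
  roi <- list(lab = roilab)
  nbsum <- rowSums(nbh$labs26)
  nbcnt <- rowSums(nbh$nodes26 > 0L)
  valid <- nbcnt > 0L
  nvp <- sum(valid)
  lab <- roi$lab[valid]
  abar <- nbsum[valid] / nbcnt[valid]
  n_i <- tabulate(lab, nbins = ng)
  p_i <- n_i / nvp
  s_i <- vapply(seq_len(ng), function(i) {
    sel <- lab == i
    if (any(sel)) sum(abs(i - abar[sel])) else 0
  }, numeric(1))

  levels_present <- which(p_i > 0)
  ngp <- length(levels_present)
  ii <- levels_present
  pi_ <- p_i[ii]
  si_ <- s_i[ii]

  denom_co <- sum(pi_ * si_)
  coarseness <- if (denom_co > 0) min(1 / denom_co, 1e6) else 1e6

  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(ii, ii, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(si_) / nvp)
  } else 0

  ipi <- ii * pi_
  denom_bus <- sum(abs(outer(ipi, ipi, `-`)))
  busyness <- if (denom_bus > 0) sum(pi_ * si_) / denom_bus else 0

  pis <- pi_ * si_
  complexity <- if (nvp > 0) {
    num <- abs(outer(ii, ii, `-`)) * (outer(pis, rep(1, ngp)) +
                                        outer(rep(1, ngp), pis)) /
      (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))
    sum(num) / nvp
  } else 0

  denom_str <- sum(si_)
  strength <- if (denom_str > 0) {
    sum((outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_)) *
          outer(ii, ii, `-`)^2) / denom_str
  } else 0

  out <- c(coarseness, contrast, busyness, complexity, strength)
  names(out) <- ngtdm_feature_names()
  out
}

## ------------------------------------------------- combined extraction ----

# All five texture families from one discretized ROI, sharing the ROI index
# and neighborhood precomputation (used by the bulk extractor; the exported
# per-family functions recompute it independently).
texture_features_combined <- function(disc) {
  roi <- roi_voxel_index(disc$labels)
  ng <- disc$n_levels
  nbh <- texture_neighborhood(disc$labels, roi)
  n_roi <- length(roi$lin)

  glcm <- glcm_features_impl(roi$lab, nbh$labs26[, 1:13, drop = FALSE], ng)

  dirs <- texture_directions()
  acc <- 0
  for (q in seq_len(nrow(dirs))) {
    P <- glrlm_matrix(disc$labels, roi, dirs[q, ], ng)
    acc <- acc + szm_style_features(P, n_roi)
  }
  glrlm <- acc / nrow(dirs)
  names(glrlm) <- glrlm_feature_names()

  szm <- szm_style_features(glszm_matrix_from_nbh(roi$lab, nbh, ng), n_roi)
  names(szm) <- glszm_feature_names()

  f <- szm_style_features(gldm_matrix_from_nbh(roi$lab, nbh, ng), n_roi)
  gldm <- c(f["sre"], f["lre"], f["gln"], f["rln"], f["rlnn"], f["glv"],
            f["rv"])
  names(gldm) <- gldm_feature_names()

  ngtdm <- ngtdm_features_impl(roi$lab, nbh, ng)

  c(glcm, glrlm, szm, gldm, ngtdm)
}
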