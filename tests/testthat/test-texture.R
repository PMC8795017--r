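# Hand-checkable cases plus randomized brute-force oracle equivalence for
# every texture matrix family.

test_that("GLCM worked examples", {
  # two rows of equal labels: along-row pairs are (1,1) and (2,2) only
  lab <- array(c(1L, 2L, 1L, 2L), c(2, 2, 1))  # column-major: rows 1/2
  roi <- labradiomics:::roi_voxel_index(lab)
  nbh <- labradiomics:::texture_neighborhood(lab, roi)
  p <- labradiomics:::glcm_matrix_from_nb(roi$lab, nbh$labs26[, 2], 2)
  expect_equal(p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  f <- labradiomics:::glcm_features_one(p)
  names(f) <- sub("GLCM_", "", labradiomics:::glcm_feature_names())
  expect_equal(f[["contrast"]], 0)

  # constant ROI: energy 1, entropy 0, contrast 0
  disc <- disc_from_labels(array(1L, c(3, 3, 3)), 1L)
  g <- glcm_features(disc)
  expect_equal(g[["GLCM_joint_energy"]], 1)
  expect_equal(g[["GLCM_joint_entropy"]], 0)
  expect_equal(g[["GLCM_contrast"]], 0)

  # 4x4 checkerboard: all horizontal neighbors differ by one level
  cb <- array(0L, c(4, 4, 1))
  cb[, , 1] <- (outer(1:4, 1:4, `+`) %% 2) + 1L
  roi <- labradiomics:::roi_voxel_index(cb)
  nbh <- labradiomics:::texture_neighborhood(cb, roi)
  ph <- labradiomics:::glcm_matrix_from_nb(roi$lab, nbh$labs26[, 1], 2)
  fh <- labradiomics:::glcm_features_one(ph)
  names(fh) <- sub("GLCM_", "", labradiomics:::glcm_feature_names())
  expect_equal(fh[["contrast"]], 1)
})

test_that("GLCM equals brute-force pair enumeration on random grids", {
  set.seed(20)
  dirs <- labradiomics:::texture_directions()
  for (rep in 1:40) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lab <- random_label_grid(dims, ng)
    if (sum(lab > 0) < 2) next
    roi <- labradiomics:::roi_voxel_index(lab)
    nbh <- labradiomics:::texture_neighborhood(lab, roi)
    for (q in sample(13, 4)) {
      got <- labradiomics:::glcm_matrix_from_nb(roi$lab, nbh$labs26[, q], ng)
      ref <- oracle_glcm(lab, dirs[q, ], ng)
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("GLRLM worked examples and the run-sum invariant", {
  # constant 3x3x3 ROI: one run of length 3 on every grid line
  lab <- array(1L, c(3, 3, 3))
  roi <- labradiomics:::roi_voxel_index(lab)
  P <- labradiomics:::glrlm_matrix(lab, roi, c(1, 0, 0), 1L)
  expect_equal(P, matrix(c(0, 0, 9), 1, 3))

  # all-distinct labels along a line: unit runs only
  lab2 <- array(0L, c(4, 1, 1))
  lab2[, 1, 1] <- 1:4
  roi2 <- labradiomics:::roi_voxel_index(lab2)
  P2 <- labradiomics:::glrlm_matrix(lab2, roi2, c(1, 0, 0), 4L)
  expect_equal(P2, matrix(c(1, 1, 1, 1), 4, 1))
  f2 <- labradiomics:::szm_style_features(P2, 4)
  expect_equal(unname(f2["rln"]), 16 / 4)  # 4 runs all of length 1

  # total weighted run length per direction = ROI voxel count
  set.seed(21)
  dirs <- labradiomics:::texture_directions()
  for (rep in 1:10) {
    lab <- random_label_grid(sample(3:6, 3, TRUE), 3)
    if (sum(lab > 0) < 2) next
    roi <- labradiomics:::roi_voxel_index(lab)
    for (q in 1:13) {
      P <- labradiomics:::glrlm_matrix(lab, roi, dirs[q, ], 3L)
      lens <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
      expect_equal(sum(P * lens), sum(lab > 0))
    }
  }
})

test_that("GLRLM equals brute-force line walking on random grids", {
  set.seed(22)
  dirs <- labradiomics:::texture_directions()
  for (rep in 1:40) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lab <- random_label_grid(dims, ng)
    if (sum(lab > 0) < 2) next
    roi <- labradiomics:::roi_voxel_index(lab)
    for (q in sample(13, 4)) {
      got <- labradiomics:::glrlm_matrix(lab, roi, dirs[q, ], ng)
      ref <- oracle_glrlm(lab, dirs[q, ], ng)
      # implementations may differ in trailing all-zero length columns
      maxl <- max(ncol(got), ncol(ref))
      pad <- function(P) cbind(P, matrix(0, nrow(P), maxl - ncol(P)))
      expect_equal(pad(got), pad(ref), tolerance = 1e-12)
    }
  }
})

test_that("GLSZM worked example and brute-force zone equivalence", {
  # constant 3x3x3 ROI: a single zone of size 27
  disc <- disc_from_labels(array(1L, c(3, 3, 3)), 1L)
  f <- glszm_features(disc)
  expect_equal(f[["GLSZM_zp"]], 1 / 27)
  expect_equal(f[["GLSZM_lae"]], 27^2)

  set.seed(23)
  for (rep in 1:40) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lab <- random_label_grid(dims, ng)
    if (sum(lab > 0) < 2) next
    roi <- labradiomics:::roi_voxel_index(lab)
    nbh <- labradiomics:::texture_neighborhood(lab, roi)
    got <- labradiomics:::glszm_matrix_from_nbh(roi$lab, nbh, ng)
    ref <- oracle_glszm(lab, ng)
    maxl <- max(ncol(got), ncol(ref))
    pad <- function(P) cbind(P, matrix(0, nrow(P), maxl - ncol(P)))
    expect_equal(pad(got), pad(ref), tolerance = 1e-12)
  }
})

test_that("GLDM equals brute-force dependence counting", {
  set.seed(24)
  for (rep in 1:25) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lab <- random_label_grid(dims, ng)
    if (sum(lab > 0) < 2) next
    roi <- labradiomics:::roi_voxel_index(lab)
    nbh <- labradiomics:::texture_neighborhood(lab, roi)
    got <- labradiomics:::gldm_matrix_from_nbh(roi$lab, nbh, ng)
    ref <- oracle_gldm(lab, ng)
    maxl <- max(ncol(got), ncol(ref))
    pad <- function(P) cbind(P, matrix(0, nrow(P), maxl - ncol(P)))
    expect_equal(pad(got), pad(ref), tolerance = 1e-12)
  }
})

test_that("NGTDM degenerate and simple cases", {
  # constant ROI: zero tone difference, coarseness capped
  disc <- disc_from_labels(array(1L, c(3, 3, 3)), 1L)
  f <- ngtdm_features(disc)
  expect_equal(f[["NGTDM_coarseness"]], 1e6)
  expect_equal(f[["NGTDM_contrast"]], 0)
  expect_equal(f[["NGTDM_busyness"]], 0)

  # two-level 2x1x1 ROI: each voxel's only neighbor is the other level
  lab <- array(c(1L, 2L), c(2, 1, 1))
  f2 <- ngtdm_features(disc_from_labels(lab, 2L))
  # s_1 = |1-2| = 1, s_2 = |2-1| = 1, p = (0.5, 0.5), Nvp = 2
  expect_equal(f2[["NGTDM_coarseness"]], 1 / (0.5 * 1 + 0.5 * 1))
  expect_equal(f2[["NGTDM_contrast"]], (0.5 * 0.5 * 1 / (2 * 1)) * (2 / 2) * 2)
})

test_that("texture features are finite on fuzzed inputs", {
  set.seed(25)
  for (rep in 1:15) {
    dims <- sample(2:5, 3, replace = TRUE)
    ng <- sample(1:5, 1)
    lab <- random_label_grid(dims, ng, p_roi = stats::runif(1, 0.2, 1))
    if (sum(lab > 0) < 1) next
    disc <- disc_from_labels(lab, as.integer(max(lab)))
    if (disc$n_levels < 1) next
    out <- labradiomics:::texture_features_combined(disc)
    expect_length(out, 26 + 16 + 16 + 7 + 5)
    expect_true(all(is.finite(out)))
  }
})
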