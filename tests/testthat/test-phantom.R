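test_that("phantom generation is deterministic and class effects are causal", {
  p <- tiny_phantom()
  a <- generate_phantom(p, "control", seed = 7)
  b <- generate_phantom(p, "control", seed = 7)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_false(identical(a$image$data,
                         generate_phantom(p, "control", seed = 8)$image$data))

  # all-zero effect and no noise: the two classes are indistinguishable
  p0 <- tiny_phantom(noise_sigma = 0, texture_sigma = 0,
                     subject_jitter_sd = 0)
  ctl <- generate_phantom(p0, "control", effect = null_effect(), seed = 3)
  pat <- generate_phantom(p0, "patient", effect = null_effect(), seed = 3)
  expect_identical(ctl$image$data, pat$image$data)

  # a nonzero focal effect darkens patient ROIs only
  eff <- class_effect(focal_hypointensity_delta = 10, focal_fraction = 0.2)
  pat2 <- generate_phantom(p0, "patient", effect = eff, seed = 3)
  expect_identical(ctl$mask$data, pat2$mask$data)
  expect_lt(sum(pat2$image$data), sum(ctl$image$data))
})

test_that("mask volume matches the closed-form solid volume", {
  # fine grid so voxelization error is small; solids are disjoint by design
  p <- phantom_params(grid_shape = c(96L, 96L, 96L),
                      spacing = c(0.25, 0.25, 0.25),
                      noise_sigma = 0, texture_sigma = 0,
                      subject_jitter_sd = 0)
  m <- generate_phantom(p, "control", seed = 1)$mask
  v_vox <- sum(m$data) * prod(m$spacing)
  v_ana <- 4 / 3 * pi * prod(p$vestibule_radii) +
    3 * pi^2 * p$canal_radius * p$canal_tube_radius^2
  expect_lt(abs(v_vox / v_ana - 1), 0.05)
})

test_that("oversized geometry errors name the offending radius", {
  expect_error(phantom_params(grid_shape = c(16L, 16L, 16L),
                              vestibule_radii = c(10, 3, 3)),
               "vestibule_radii")
  expect_error(phantom_params(grid_shape = c(32L, 32L, 32L),
                              canal_radius = 9),
               "canal_radius")
  expect_error(phantom_params(noise_sigma = -1), "noise_sigma")
})

test_that("rician noise yields nonnegative magnitude images", {
  p <- tiny_phantom(rician = TRUE, background_mean = 0, noise_sigma = 3)
  img <- generate_phantom(p, "control", seed = 2)$image
  expect_true(all(img$data >= 0))
})

test_that("generate_cohort writes NIfTI pairs and a consistent table", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = c(A = 2L, D = 1L),
                      n_controls = c(A = 1L, D = 2L),
                      seed = 11, phantom = tiny_phantom(),
                      centers = default_centers()[c("A", "D")])
  tab <- generate_cohort(spec, dir)
  expect_equal(nrow(tab), 6)
  expect_identical(sort(unique(tab$label)), c("control", "patient"))
  expect_true(all(file.exists(tab$image_path)))
  expect_true(all(file.exists(tab$mask_path)))
  csv <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  expect_identical(csv$id, tab$id)

  # round trip preserves grid, spacing and mask content
  img <- read_nifti_volume(tab$image_path[1])
  msk <- read_nifti_mask(tab$mask_path[1])
  ref <- generate_phantom(spec$phantom, label = tab$label[1],
                          effect = spec$effect, center = spec$centers$A,
                          seed = labradiomics:::cohort_schedule(spec)$seed[1])
  expect_equal(img$spacing, ref$image$spacing, tolerance = 1e-6)
  expect_identical(msk$data, ref$mask$data)
  expect_equal(img$data, ref$image$data, tolerance = 1e-6)

  # empty spec: empty table, no volumes written
  dir2 <- withr::local_tempdir()
  empty <- cohort_spec(n_patients = c(A = 0L, D = 0L),
                       n_controls = c(A = 0L, D = 0L),
                       phantom = tiny_phantom(),
                       centers = default_centers()[c("A", "D")])
  tab2 <- generate_cohort(empty, dir2)
  expect_equal(nrow(tab2), 0)
  expect_length(list.files(dir2, pattern = "nii"), 0)
})

test_that("cohort schedule ids and geometry are seed-invariant", {
  spec1 <- cohort_spec(n_patients = c(A = 2L, D = 1L),
                       n_controls = c(A = 1L, D = 1L), seed = 1,
                       phantom = tiny_phantom(),
                       centers = default_centers()[c("A", "D")])
  spec2 <- spec1
  spec2$seed <- 2L
  s1 <- labradiomics:::cohort_schedule(spec1)
  s2 <- labradiomics:::cohort_schedule(spec2)
  expect_identical(s1[, c("id", "label", "center")],
                   s2[, c("id", "label", "center")])
  expect_false(identical(s1$seed, s2$seed))
})

test_that("default cohort counts reproduce the four-center study table", {
  spec <- cohort_spec()
  sched <- labradiomics:::cohort_schedule(spec)
  expect_equal(nrow(sched), 260)
  expect_equal(sum(sched$label == "patient"), 120)
  expect_equal(sum(sched$label == "control"), 140)
  expect_equal(sum(sched$center == "D"), 24)
})
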