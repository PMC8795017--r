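#' Parameters of the synthetic labyrinth phantom
#'
#' The phantom is a minimal solid with labyrinth-like topology: a vestibule
#' modelled as an ellipsoid plus three mutually orthogonal half-torus arcs
#' standing in for the semicircular canals. The arcs are offset along their
#' plane normals and restricted to disjoint half-spaces so that, by
#' construction, the four solids do not overlap and the total volume has the
#' closed form 4/3*pi*a*b*c + 3*pi^2*R*r^2.
#'
#' The fluid-filled labyrinth is bright on T2-weighted imaging, so the ROI
#' mean sits well above the background. Within-ROI texture is modelled as
#' Gaussian white noise smoothed to a correlation length `texture_corr_mm`
#' and scaled to `texture_sigma`; independent acquisition noise of SD
#' `noise_sigma` (Gaussian, optionally Rician magnitude) is added everywhere.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, voxel size in mm.
#' @param vestibule_radii ellipsoid semi-axes in mm.
#' @param canal_radius torus major radius in mm (shared by the three arcs).
#' @param canal_tube_radius torus minor (tube) radius in mm.
#' @param canal_offset_mm offset of each canal plane from the vestibule
#'   centre along its normal, in mm.
#' @param roi_intensity_mean,background_mean intensity levels (arbitrary
#'   units) inside and outside the labyrinth.
#' @param texture_sigma SD of the smoothed intra-ROI texture field.
#' @param texture_corr_mm correlation length (Gaussian kernel SD, mm) of the
#'   texture field.
#' @param noise_sigma SD of the additive acquisition noise.
#' @param rician if `TRUE`, noise is applied as a Rician magnitude
#'   (`sqrt((signal + n1)^2 + n2^2)`) as in magnitude MR reconstruction;
#'   otherwise plain additive Gaussian.
#' @param subject_jitter_sd lognormal SD of per-subject anatomical size
#'   variation applied multiplicatively to all radii (0 disables).
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(48L, 48L, 48L),
                           spacing = c(0.5, 0.5, 0.5),
                           vestibule_radii = c(4.0, 3.2, 2.8),
                           canal_radius = 5.6,
                           canal_tube_radius = 0.9,
                           canal_offset_mm = 2.0,
                           roi_intensity_mean = 100,
                           background_mean = 30,
                           texture_sigma = 1.5,
                           texture_corr_mm = 1.0,
                           noise_sigma = 2,
                           rician = FALSE,
                           subject_jitter_sd = 0.02) {
  p <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
            vestibule_radii = as.numeric(vestibule_radii),
            canal_radius = canal_radius, canal_tube_radius = canal_tube_radius,
            canal_offset_mm = canal_offset_mm,
            roi_intensity_mean = roi_intensity_mean,
            background_mean = background_mean,
            texture_sigma = texture_sigma, texture_corr_mm = texture_corr_mm,
            noise_sigma = noise_sigma, rician = isTRUE(rician),
            subject_jitter_sd = subject_jitter_sd)
  if (any(p$vestibule_radii <= 0)) stop("vestibule_radii must be positive")
  if (p$canal_radius <= 0) stop("canal_radius must be positive")
  if (p$canal_tube_radius <= 0) stop("canal_tube_radius must be positive")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  check_phantom_fits(p)
  class(p) <- "phantom_params"
  p
}

check_phantom_fits <- function(p, scale = 1) {
  half <- (p$grid_shape - 1) * p$spacing / 2
  need_v <- p$vestibule_radii * scale
  if (any(need_v > half))
    stop(sprintf("vestibule_radii (%.2f mm) exceed half grid extent (%.2f mm)",
                 max(need_v), min(half[need_v > half])))
  need_c <- (p$canal_radius + p$canal_tube_radius) * scale + p$canal_offset_mm
  if (any(need_c > half))
    stop(sprintf("canal_radius + canal_tube_radius + offset (%.2f mm) exceed half grid extent (%.2f mm)",
                 need_c, min(half)))
  invisible(TRUE)
}

#' Class effect applied to patient phantoms
#'
#' Encodes the image-level differences planted between the two classes. The
#' defaults describe the "strong" effect used for power/recovery
#' experiments: a focal intensity drop in a saccule-like sub-region of the
#' vestibule, three times the acquisition noise SD, covering 15% of the ROI
#' volume. Setting every field to 0 yields identically distributed classes.
#'
#' @param focal_hypointensity_delta intensity reduction (same units as the
#'   phantom intensities) applied inside the focal sub-region of patients.
#' @param focal_fraction target fraction of ROI volume affected, in `[0,1]`.
#' @param texture_corr_length_shift additive change (mm) to the texture
#'   correlation length for patients.
#' @param shape_dilation_mm radial inflation (mm) of all patient ROI solids.
#' @return A `class_effect` list.
#' @export
class_effect <- function(focal_hypointensity_delta = 6,
                         focal_fraction = 0.15,
                         texture_corr_length_shift = 0,
                         shape_dilation_mm = 0) {
  if (focal_fraction < 0 || focal_fraction > 1)
    stop("focal_fraction must lie in [0, 1]")
  structure(list(focal_hypointensity_delta = focal_hypointensity_delta,
                 focal_fraction = focal_fraction,
                 texture_corr_length_shift = texture_corr_length_shift,
                 shape_dilation_mm = shape_dilation_mm),
            class = "class_effect")
}

#' @rdname class_effect
#' @export
null_effect <- function() {
  class_effect(0, 0, 0, 0)
}

#' Per-center acquisition effect
#'
#' Scanner/protocol differences between centers are modelled as an affine
#' intensity transform plus a center-specific (possibly anisotropic)
#' acquisition voxel spacing.
#'
#' @param intensity_scale multiplicative intensity factor (> 0).
#' @param intensity_offset additive intensity offset.
#' @param spacing acquisition voxel spacing in mm (length 3).
#' @return A `center_effect` list.
#' @export
center_effect <- function(intensity_scale = 1, intensity_offset = 0,
                          spacing = c(0.5, 0.5, 0.5)) {
  if (intensity_scale <= 0) stop("intensity_scale must be positive")
  structure(list(intensity_scale = intensity_scale,
                 intensity_offset = intensity_offset,
                 spacing = as.numeric(spacing)),
            class = "center_effect")
}

#' Default four-center acquisition effects
#'
#' Emulates a four-center study (A-D) with distinct intensity scales and
#' offsets and center-specific anisotropic voxel spacings. The external
#' test center D has its own acquisition profile, chosen within the range
#' spanned by the training centers: intensity differences are removed
#' exactly by Z-score normalization, and interpolation effects of
#' resampling center D are then representable from the training centers, so
#' a correctly harmonized pipeline can generalize to it.
#'
#' @return Named list of four [center_effect()] objects.
#' @export
default_centers <- function() {
  list(
    A = center_effect(1.00, 0,   c(0.50, 0.50, 0.60)),
    B = center_effect(1.15, 15,  c(0.45, 0.45, 0.65)),
    C = center_effect(0.90, -10, c(0.55, 0.55, 0.50)),
    D = center_effect(1.05, 5,   c(0.50, 0.50, 0.55))
  )
}

#' Specification of a synthetic multi-center cohort
#'
#' @param n_patients,n_controls named integer vectors (one entry per center)
#'   of ears per class. Defaults reproduce the four-center study cohort:
#'   patients A 48, B 33, C 33, D 6 (120) and controls A 23, B 24, C 75,
#'   D 18 (140), 260 ears in total with 24 ears at center D.
#' @param seed master seed; regenerating with the same seed reproduces
#'   byte-identical volumes.
#' @param phantom a [phantom_params()].
#' @param effect a [class_effect()] applied to patients.
#' @param centers named list of [center_effect()], names matching the count
#'   vectors.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = c(A = 48L, B = 33L, C = 33L, D = 6L),
                        n_controls = c(A = 23L, B = 24L, C = 75L, D = 18L),
                        seed = 1L,
                        phantom = phantom_params(),
                        effect = class_effect(),
                        centers = default_centers()) {
  if (is.null(names(n_patients)) || is.null(names(n_controls)))
    stop("per-center counts must be named")
  if (!setequal(names(n_patients), names(n_controls)))
    stop("patient and control counts must cover the same centers")
  if (any(n_patients < 0) || any(n_controls < 0)) stop("counts must be >= 0")
  if (!all(names(n_patients) %in% names(centers)))
    stop("missing center_effect for some centers")
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 seed = as.integer(seed), phantom = phantom, effect = effect,
                 centers = centers),
            class = "cohort_spec")
}

# Implicit-solid voxelization of the labyrinth phantom. Returns the binary
# mask plus metadata reused by the intensity model.
phantom_geometry <- function(p, center_spacing, scale = 1, dilate_mm = 0) {
  gs <- p$grid_shape
  sp <- center_spacing
  ctr <- (gs - 1) * sp / 2
  x <- ((seq_len(gs[1]) - 1) * sp[1]) - ctr[1]
  y <- ((seq_len(gs[2]) - 1) * sp[2]) - ctr[2]
  z <- ((seq_len(gs[3]) - 1) * sp[3]) - ctr[3]
  X <- array(rep(x, times = gs[2] * gs[3]), gs)
  Y <- array(rep(rep(y, each = gs[1]), times = gs[3]), gs)
  Z <- array(rep(z, each = gs[1] * gs[2]), gs)

  vr <- p$vestibule_radii * scale + dilate_mm
  R <- p$canal_radius * scale
  r <- p$canal_tube_radius * scale + dilate_mm
  off <- p$canal_offset_mm

  mask <- (X / vr[1])^2 + (Y / vr[2])^2 + (Z / vr[3])^2 <= 1

  # Lateral-like canal: ring in a z-plane above the vestibule, arc at x >= 0.
  rad <- sqrt(X^2 + Y^2)
  mask <- mask | ((rad - R)^2 + (Z - off)^2 <= r^2 & X >= 0)
  # Posterior-like canal: ring in an x-plane, arc at y <= 0.
  rad <- sqrt(Y^2 + Z^2)
  mask <- mask | ((rad - R)^2 + (X + off)^2 <= r^2 & Y <= 0)
  # Superior-like canal: ring in a y-plane, arc at x <= 0.
  rad <- sqrt(X^2 + Z^2)
  mask <- mask | ((rad - R)^2 + (Y - off)^2 <= r^2 & X <= 0)

  list(mask = array(as.integer(mask), gs), X = X, Y = Y, Z = Z,
       vestibule_radii = vr)
}

# Closed-form volume of the phantom solids (disjoint by construction).
phantom_analytic_volume <- function(p, scale = 1) {
  vr <- p$vestibule_radii * scale
  4 / 3 * pi * prod(vr) +
    3 * pi^2 * (p$canal_radius * scale) * (p$canal_tube_radius * scale)^2
}

#' Generate one synthetic labyrinth phantom
#'
#' Voxelizes the phantom solids on the center's acquisition grid, fills in
#' the two-tissue intensity model with class and center effects, and adds
#' noise. Deterministic given `seed`.
#'
#' @param params a [phantom_params()].
#' @param label `"patient"` or `"control"`; class effects apply to patients
#'   only.
#' @param effect a [class_effect()].
#' @param center a [center_effect()] (its spacing overrides
#'   `params$spacing`); `NULL` keeps the phantom's own spacing and identity
#'   intensity transform.
#' @param seed integer seed.
#' @return list with elements `image` ([image_volume()]) and `mask`
#'   ([seg_mask()]).
#' @export
generate_phantom <- function(params, label = c("control", "patient"),
                             effect = null_effect(), center = NULL,
                             seed = 1L) {
  label <- match.arg(label)
  if (is.null(center)) center <- center_effect(spacing = params$spacing)
  sp <- center$spacing

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  scale <- if (params$subject_jitter_sd > 0)
    exp(stats::rnorm(1, 0, params$subject_jitter_sd)) else 1
  check_phantom_fits(modifyList(params, list(spacing = sp)), scale = scale)

  is_patient <- label == "patient"
  dil <- if (is_patient) effect$shape_dilation_mm else 0
  geo <- phantom_geometry(params, sp, scale = scale, dilate_mm = dil)
  gs <- params$grid_shape
  inside <- geo$mask == 1L

  img <- array(params$background_mean, gs)
  img[inside] <- params$roi_intensity_mean

  # Correlated intra-ROI texture.
  if (params$texture_sigma > 0) {
    corr <- params$texture_corr_mm +
      if (is_patient) effect$texture_corr_length_shift else 0
    corr <- max(corr, 0)
    field <- array(stats::rnorm(prod(gs)), gs)
    if (corr > 0) {
      sig_vox <- corr / sp
      field <- gaussian_smooth3(field, sig_vox) / gaussian_kernel_l2(sig_vox)
    }
    img[inside] <- img[inside] + params$texture_sigma * field[inside]
  }

  # Focal hypointense sub-region (saccule-like) in patients.
  if (is_patient && effect$focal_fraction > 0 &&
      effect$focal_hypointensity_delta != 0) {
    v_roi <- phantom_analytic_volume(params, scale = scale)
    r_f <- (3 * effect$focal_fraction * v_roi / (4 * pi))^(1 / 3)
    fc <- geo$vestibule_radii * c(0.20, 0.20, -0.15)  # inside the vestibule
    focal <- (geo$X - fc[1])^2 + (geo$Y - fc[2])^2 + (geo$Z - fc[3])^2 <= r_f^2
    sel <- focal & inside
    img[sel] <- img[sel] - effect$focal_hypointensity_delta
  }

  # Center affine intensity transform, then acquisition noise.
  img <- center$intensity_scale * img + center$intensity_offset
  if (params$noise_sigma > 0) {
    s <- params$noise_sigma * center$intensity_scale
    if (params$rician) {
      n1 <- array(stats::rnorm(prod(gs), 0, s), gs)
      n2 <- array(stats::rnorm(prod(gs), 0, s), gs)
      img <- sqrt((img + n1)^2 + n2^2)
    } else {
      img <- img + array(stats::rnorm(prod(gs), 0, s), gs)
    }
  }

  list(image = image_volume(img, spacing = sp),
       mask = seg_mask(geo$mask, spacing = sp))
}

# Deterministic per-ear schedule of a cohort: ids, labels, centers, seeds.
cohort_schedule <- function(spec) {
  rows <- list()
  for (cn in names(spec$n_patients)) {
    np <- spec$n_patients[[cn]]
    nc <- spec$n_controls[[cn]]
    if (np > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        center = cn, label = "patient", k = seq_len(np),
        stringsAsFactors = FALSE)
    if (nc > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        center = cn, label = "control", k = seq_len(nc),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(id = character(), label = character(),
                      center = character(), seed = integer(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab$id <- sprintf("%s_%s_%03d", tab$center,
                    ifelse(tab$label == "patient", "MD", "CTL"), tab$k)
  tab$seed <- derive_seeds(spec$seed, nrow(tab))
  tab[, c("id", "label", "center", "seed")]
}

#' Generate a synthetic cohort on disk
#'
#' Writes one NIfTI image and one NIfTI mask per ear plus a cohort CSV with
#' columns `id,label,center,image_path,mask_path`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir writable output directory (created if missing).
#' @return Invisibly, the cohort table (data.frame) that was written to
#'   `file.path(out_dir, "cohort.csv")`.
#' @export
generate_cohort <- function(spec, out_dir) {
  sched <- cohort_schedule(spec)
  if (anyDuplicated(sched$id)) stop("duplicate sample ids in cohort schedule")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tab <- sched[, c("id", "label", "center")]
  tab$image_path <- character(nrow(tab))
  tab$mask_path <- character(nrow(tab))
  for (i in seq_len(nrow(sched))) {
    ear <- generate_phantom(spec$phantom, label = sched$label[i],
                            effect = spec$effect,
                            center = spec$centers[[sched$center[i]]],
                            seed = sched$seed[i])
    ip <- file.path(out_dir, paste0(sched$id[i], "_img.nii.gz"))
    mp <- file.path(out_dir, paste0(sched$id[i], "_mask.nii.gz"))
    write_nifti(ear$image, ip)
    write_nifti(ear$mask, mp)
    tab$image_path[i] <- ip
    tab$mask_path[i] <- mp
  }
  utils::write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  invisible(tab)
}
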