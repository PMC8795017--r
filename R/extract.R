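texture_group_names <- function() {
  c(firstorder_feature_names(), glcm_feature_names(), glrlm_feature_names(),
    glszm_feature_names(), gldm_feature_names(), ngtdm_feature_names())
}

wavelet_band_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

#' The 812-feature roster
#'
#' The ordered list of all feature names produced by [extract_all()]:
#' 20 shape features plus 88 intensity/texture features (18 first-order,
#' 26 GLCM, 16 GLRLM, 16 GLSZM, 7 GLDM, 5 NGTDM) on the original image and
#' on each of the eight stationary wavelet sub-bands:
#' 20 + 9 x 88 = 812. Original-image features carry no prefix (e.g.
#' `Stats_min`); sub-band features are prefixed `wavelet_LLL_` etc.
#'
#' @param as_table if `TRUE`, return a data.frame with columns `name`,
#'   `image_type`, `group` instead of the bare name vector.
#' @return Character vector of 812 unique names (or the annotated table).
#' @export
feature_roster <- function(as_table = FALSE) {
  tex <- texture_group_names()
  nm <- c(shape_feature_names(), tex,
          unlist(lapply(wavelet_band_names(), function(b)
    paste0("wavelet_", b, "_", tex))))
  if (!as_table) return(nm)
  grp <- sub("_.*$", "", c(shape_feature_names(), rep(tex, 9)))
  itype <- c(rep("orig", 20 + 88),
             rep(paste0("wavelet-", wavelet_band_names()), each = 88))
  data.frame(name = nm, image_type = itype, group = grp,
             stringsAsFactors = FALSE)
}

#' Default feature-extraction configuration
#'
#' @param bin_width fixed discretization bin width (normalized-intensity
#'   units) applied to the original image and, independently, to each
#'   wavelet sub-band over the ROI.
#' @param crop_margin voxels of context kept around the ROI bounding box
#'   before filtering (must cover the wavelet filter support so cropping is
#'   exact for ROI voxels).
#' @return list of extraction settings.
#' @export
extraction_config <- function(bin_width = 0.5, crop_margin = 4L) {
  list(bin_width = bin_width, crop_margin = as.integer(crop_margin))
}

texture_block <- function(img, mask, bin_width) {
  disc <- discretize(img, mask, bin_width)
  c(firstorder_features(img, mask, disc), texture_features_combined(disc))
}

#' Extract all 812 radiomic features
#'
#' Runs the complete feature engine on a preprocessed (resampled,
#' normalized) image/mask pair: shape features of the mask, then
#' first-order and texture features of the original image and of the eight
#' Coiflet-1 stationary wavelet sub-bands, each sub-band independently
#' re-discretized with the fixed bin width over the ROI. The pair is first
#' cropped to the ROI bounding box plus `crop_margin`; with a margin
#' covering the filter support this leaves every ROI feature value
#' unchanged while bounding the cost of filtering.
#'
#' @param img preprocessed [image_volume()].
#' @param mask paired [seg_mask()] (>= 27 voxels recommended).
#' @param config an [extraction_config()].
#' @return Named numeric vector of 812 finite values in roster order.
#' @export
extract_all <- function(img, mask, config = extraction_config()) {
  stopifnot_paired(img, mask)
  if (sum(mask$data) < 1) stop("empty mask")
  cr <- crop_to_mask(img, mask, margin = max(config$crop_margin, 4L))
  img <- cr$img
  mask <- cr$mask

  out <- tryCatch(shape_features(mask),
                  error = function(e) stop("shape features: ",
                                           conditionMessage(e)))
  out <- c(out, tryCatch(texture_block(img, mask, config$bin_width),
                         error = function(e) stop("original-image features: ",
                                                  conditionMessage(e))))
  bands <- wavelet_decompose(img)
  for (b in names(bands)) {
    blk <- tryCatch(texture_block(bands[[b]], mask, config$bin_width),
                    error = function(e) stop("wavelet ", b, " features: ",
                                             conditionMessage(e)))
    names(blk) <- paste0("wavelet_", b, "_", names(blk))
    out <- c(out, blk)
  }
  stopifnot(identical(names(out), feature_roster()))
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Preprocess and extract one ear
#'
#' Convenience wrapper chaining [resample_isotropic()], [znormalize()] and
#' [extract_all()].
#'
#' @param img raw [image_volume()].
#' @param mask raw paired [seg_mask()].
#' @param target_mm isotropic resampling target (mm).
#' @param znorm_scope passed to [znormalize()].
#' @param config an [extraction_config()].
#' @return Named numeric vector of 812 features.
#' @export
process_and_extract <- function(img, mask, target_mm = 0.5,
                                znorm_scope = "volume",
                                config = extraction_config()) {
  rs <- resample_isotropic(img, mask, target_mm)
  zn <- znormalize(rs$img, rs$mask, scope = znorm_scope)
  extract_all(zn, rs$mask, config)
}

#' Extract a feature table for a cohort
#'
#' Builds the ears-by-features table for a cohort given either a cohort
#' table on disk (columns `id,label,center,image_path,mask_path`, as written
#' by [generate_cohort()]) or a [cohort_spec()] that is realized in memory
#' one ear at a time (no intermediate files).
#'
#' @param cohort a [cohort_spec()] or a data.frame cohort table with file
#'   paths.
#' @param target_mm,znorm_scope,config forwarded to [process_and_extract()].
#' @param verbose print one line per ear.
#' @return data.frame with `id`, `label`, `center` plus 812 feature columns.
#' @export
extract_cohort <- function(cohort, target_mm = 0.5, znorm_scope = "volume",
                           config = extraction_config(), verbose = FALSE) {
  if (inherits(cohort, "cohort_spec")) {
    sched <- cohort_schedule(cohort)
    load_ear <- function(i) {
      generate_phantom(cohort$phantom, label = sched$label[i],
                       effect = cohort$effect,
                       center = cohort$centers[[sched$center[i]]],
                       seed = sched$seed[i])
    }
  } else {
    sched <- cohort
    load_ear <- function(i) {
      list(image = read_nifti_volume(sched$image_path[i]),
           mask = read_nifti_mask(sched$mask_path[i]))
    }
  }
  n <- nrow(sched)
  feats <- matrix(NA_real_, n, 812,
                  dimnames = list(NULL, feature_roster()))
  for (i in seq_len(n)) {
    ear <- load_ear(i)
    feats[i, ] <- process_and_extract(ear$image, ear$mask,
                                      target_mm = target_mm,
                                      znorm_scope = znorm_scope,
                                      config = config)
    if (verbose) message(sprintf("[%d/%d] %s", i, n, sched$id[i]))
  }
  cbind(data.frame(id = sched$id, label = sched$label, center = sched$center,
                   stringsAsFactors = FALSE),
        as.data.frame(feats, check.names = FALSE))
}

#' Split a feature table into metadata and feature matrix
#'
#' @param table a feature table from [extract_cohort()].
#' @return list with `meta` (id/label/center data.frame) and `x`
#'   (numeric matrix, rows named by id).
#' @export
feature_matrix <- function(table) {
  meta_cols <- c("id", "label", "center")
  x <- as.matrix(table[, setdiff(colnames(table), meta_cols), drop = FALSE])
  rownames(x) <- table$id
  list(meta = table[, intersect(meta_cols, colnames(table)), drop = FALSE],
       x = x)
}
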