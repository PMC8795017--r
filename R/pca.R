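#' Fit the standardizer and PCA model on training rows
#'
#' Standardizes every feature to zero mean / unit SD using statistics
#' learned on the training rows only, then fits a principal component
#' analysis retaining `k` components. Near-constant features (SD below
#' `1e-12`) have their SD clamped to 1, which effectively zeroes them after
#' centering instead of amplifying numerical noise. The decomposition is
#' made deterministic by a sign convention: the largest-magnitude loading
#' of each component is positive.
#'
#' @param x numeric training matrix (rows = ears, columns = features) or a
#'   feature table from [extract_cohort()].
#' @param k number of principal components to retain (default 10).
#' @return list with `standardizer` (means, sds) and `model`
#'   (`loadings` p x k, `explained_variance`, `n_train`, `center_k`).
#' @export
fit_pca <- function(x, k = 10L) {
  if (is.data.frame(x)) x <- feature_matrix(x)$x
  if (any(!is.finite(x))) stop("non-finite entries in feature matrix")
  n <- nrow(x)
  if (n <= k) stop("fewer rows than components")
  mu <- colMeans(x)
  sds <- apply(x, 2, sd_pop)
  sds[sds < 1e-12] <- 1
  standardizer <- list(mean = mu, sd = sds)
  z <- standardize_features(x, standardizer)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(L))) {
    piv <- which.max(abs(L[, j]))
    if (L[piv, j] < 0) L[, j] <- -L[, j]
  }
  model <- list(loadings = L, explained_variance = pc$sdev[seq_len(k)]^2,
                n_train = n, k = k)
  list(standardizer = standardizer, model = model)
}

standardize_features <- function(x, standardizer) {
  if (!identical(colnames(x), names(standardizer$mean)) &&
      !is.null(colnames(x)) && !is.null(names(standardizer$mean))) {
    if (!setequal(colnames(x), names(standardizer$mean)))
      stop("feature columns do not match the fitted standardizer")
    x <- x[, names(standardizer$mean), drop = FALSE]
  }
  sweep(sweep(x, 2, standardizer$mean), 2, standardizer$sd, `/`)
}

#' Project samples onto the retained principal components
#'
#' Test rows are standardized with the training statistics, never their
#' own, keeping the protocol leakage-free.
#'
#' @param x feature matrix or table ([extract_cohort()] output).
#' @param fit result of [fit_pca()].
#' @return Score matrix (n x k).
#' @export
pca_transform <- function(x, fit) {
  if (is.data.frame(x)) x <- feature_matrix(x)$x
  if (ncol(x) != nrow(fit$model$loadings)) stop("feature column mismatch")
  standardize_features(x, fit$standardizer) %*% fit$model$loadings
}

#' Reconstruct standardized features from PC scores
#'
#' @param scores n x k score matrix.
#' @param fit result of [fit_pca()].
#' @return Reconstructed standardized feature matrix (n x p).
#' @export
pca_inverse_transform <- function(scores, fit) {
  scores %*% t(fit$model$loadings)
}

#' Per-feature mean contribution across components
#'
#' Summarizes each feature's importance in the retained decomposition as
#' the mean absolute loading over the `k` components, normalized by the
#' maximum so scores live in `[0, 1]`; features above the `threshold`
#' (default 0.7) form the selected set.
#'
#' @param fit result of [fit_pca()].
#' @param threshold selection cutoff on the normalized score.
#' @return data.frame (`feature`, `contribution`, `selected`) sorted in
#'   feature order, with attribute `"selected"` giving the selected names.
#' @export
feature_contributions <- function(fit, threshold = 0.7) {
  L <- fit$model$loadings
  raw <- rowMeans(abs(L))
  score <- raw / max(raw)
  out <- data.frame(feature = rownames(L) %||% paste0("f", seq_along(raw)),
                    contribution = unname(score),
                    selected = unname(score > threshold),
                    stringsAsFactors = FALSE)
  attr(out, "selected") <- out$feature[out$selected]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
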