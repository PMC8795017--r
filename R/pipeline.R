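#' Experiment configuration
#'
#' Bundles every stage's parameters and routes all randomness through one
#' master seed: per-stage seeds (cohort generation, split, k-fold,
#' classifier, bootstrap) are derived deterministically from it, so a
#' single integer reproduces the whole experiment bit-exactly.
#'
#' @param cohort a [cohort_spec()] (realized in memory, one ear at a time)
#'   or a cohort table data.frame with `id,label,center,image_path,mask_path`.
#' @param seed master seed.
#' @param target_mm isotropic resampling target (mm).
#' @param znorm_scope `"volume"` or `"roi"` (see [znormalize()]).
#' @param bin_width discretization bin width.
#' @param n_components retained principal components.
#' @param test_center,test_fraction split protocol (see [make_split()]).
#' @param hidden_units,learning_rate,max_epochs,patience MLP settings
#'   (see [mlp_config()]).
#' @param bootstrap_ci attach bootstrap CIs to the reports.
#' @param bootstrap_reps bootstrap replicates.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(), seed = 1L,
                              target_mm = 0.5, znorm_scope = "volume",
                              bin_width = 0.5, n_components = 10L,
                              test_center = "D", test_fraction = 0.26,
                              hidden_units = 500L, learning_rate = 0.001,
                              max_epochs = 1000L, patience = 20L,
                              bootstrap_ci = FALSE, bootstrap_reps = 2000L) {
  structure(list(cohort = cohort, seed = as.integer(seed),
                 target_mm = target_mm, znorm_scope = znorm_scope,
                 bin_width = bin_width, n_components = as.integer(n_components),
                 test_center = test_center, test_fraction = test_fraction,
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 bootstrap_ci = isTRUE(bootstrap_ci),
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "experiment_config")
}

stage_seeds <- function(master) {
  s <- derive_seeds(master, 5)
  list(cohort = s[1], split = s[2], kfold = s[3], mlp = s[4], bootstrap = s[5])
}

#' Run the full experiment
#'
#' Executes the pipeline end to end: (optional) cohort synthesis ->
#' preprocessing -> 812-feature extraction -> PCA reduction fitted on the
#' training rows -> MLP training with early stopping -> evaluation on the
#' held-out center-aware test set. Stage failures abort with a stage-named
#' error. If `out_dir` is given, the feature table, contribution report,
#' metrics, ROC points and a provenance manifest are written there.
#'
#' @param config an [experiment_config()].
#' @param features optional precomputed feature table ([extract_cohort()]
#'   output) to skip re-extraction.
#' @param out_dir optional output directory.
#' @param verbose progress messages.
#' @return list with `features`, `split`, `pca` fit, `contributions`,
#'   `model`, `train_report`, `test_report`, `config`.
#' @export
run_experiment <- function(config, features = NULL, out_dir = NULL,
                           verbose = FALSE) {
  seeds <- stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (is.null(features)) {
    cohort <- config$cohort
    if (inherits(cohort, "cohort_spec")) {
      cohort$seed <- seeds$cohort
    }
    features <- stage("extract", extract_cohort(
      cohort, target_mm = config$target_mm, znorm_scope = config$znorm_scope,
      config = extraction_config(bin_width = config$bin_width),
      verbose = verbose))
  }

  split <- stage("split", make_split(features, config$test_center,
                                     config$test_fraction, seed = seeds$split))
  fm <- feature_matrix(features)
  tr <- features$id %in% split$train_ids
  te <- features$id %in% split$test_ids

  fit <- stage("reduce", fit_pca(fm$x[tr, , drop = FALSE],
                                 k = config$n_components))
  contrib <- feature_contributions(fit)
  sc_tr <- pca_transform(fm$x[tr, , drop = FALSE], fit)
  sc_te <- pca_transform(fm$x[te, , drop = FALSE], fit)

  mcfg <- mlp_config(hidden_units = config$hidden_units,
                     learning_rate = config$learning_rate,
                     max_epochs = config$max_epochs,
                     patience = config$patience, seed = seeds$mlp)
  model <- stage("train", mlp_train(sc_tr, fm$meta$label[tr], mcfg))

  p_tr <- mlp_predict_proba(model, sc_tr)[, "patient"]
  p_te <- mlp_predict_proba(model, sc_te)[, "patient"]
  train_report <- stage("evaluate", metrics_report(
    fm$meta$label[tr], p_tr, ci = config$bootstrap_ci,
    reps = config$bootstrap_reps, seed = seeds$bootstrap,
    protocol = "train"))
  test_report <- stage("evaluate", metrics_report(
    fm$meta$label[te], p_te, ci = config$bootstrap_ci,
    reps = config$bootstrap_reps, seed = seeds$bootstrap,
    protocol = "test"))

  out <- list(features = features, split = split, pca = fit,
              contributions = contrib, model = model,
              train_report = train_report, test_report = test_report,
              config = config)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' Stratified k-fold cross-validation of the pipeline tail
#'
#' Re-runs reduction + classification on each fold of a precomputed feature
#' table (features are extracted once; PCA and the MLP are refit per fold
#' on the training part only).
#'
#' @param features a feature table from [extract_cohort()].
#' @param config an [experiment_config()].
#' @param k folds (default 10).
#' @return list with per-fold `reports` and `mean_metrics`.
#' @export
run_crossval <- function(features, config, k = 10L) {
  seeds <- stage_seeds(config$seed)
  folds <- kfold_plan(features, k = k, seed = seeds$kfold)
  fm <- feature_matrix(features)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    te <- features$id %in% folds[[f]]
    tr <- !te
    fit <- fit_pca(fm$x[tr, , drop = FALSE], k = config$n_components)
    sc_tr <- pca_transform(fm$x[tr, , drop = FALSE], fit)
    sc_te <- pca_transform(fm$x[te, , drop = FALSE], fit)
    mcfg <- mlp_config(hidden_units = config$hidden_units,
                       learning_rate = config$learning_rate,
                       max_epochs = config$max_epochs,
                       patience = config$patience,
                       seed = seeds$mlp + f)
    model <- mlp_train(sc_tr, fm$meta$label[tr], mcfg)
    p_te <- mlp_predict_proba(model, sc_te)[, "patient"]
    reports[[f]] <- metrics_report(fm$meta$label[te], p_te,
                                   protocol = sprintf("CV-fold-%d", f))
  }
  mm <- Reduce(`+`, lapply(reports, function(r) r$metrics)) / k
  list(reports = reports, mean_metrics = mm)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$contributions,
                   file.path(out_dir, "contributions.csv"), row.names = FALSE)
  report <- list(train = result$train_report[c("confusion", "metrics", "n")],
                 test = result$test_report[c("confusion", "metrics", "n")])
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("labradiomics")),
    seed = result$config$seed,
    config_hash = config_hash(result$config),
    n_features = length(feature_roster()),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(feature_roster(as_table = TRUE),
                       file.path(out_dir, "roster.json"))
  invisible(out_dir)
}

config_hash <- function(config) {
  cfg <- config
  cfg$cohort <- NULL
  paste0("c", sum(utils::head(
    as.integer(charToRaw(paste(deparse(cfg), collapse = ""))), 1e4)))
}
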