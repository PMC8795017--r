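#' Center-aware train/test split
#'
#' Reproduces the study's evaluation split: the entire external test center
#' goes to the test set, which is then topped up with a seeded random draw
#' from the remaining centers until it holds `test_fraction` of the cohort
#' (rounded); everything else trains. Train and test are disjoint.
#'
#' @param cohort data.frame with at least `id` and `center` columns.
#' @param test_center center identifier held out entirely (default "D").
#' @param test_fraction fraction of ears in the test set (default 0.26).
#' @param seed RNG seed for the random complement.
#' @return list with `train_ids`, `test_ids` and a `meta` record.
#' @export
make_split <- function(cohort, test_center = "D", test_fraction = 0.26,
                       seed = 1L) {
  if (!test_center %in% cohort$center)
    stop("test_center not present in cohort: ", test_center)
  if (length(unique(cohort$center)) < 2)
    stop("cohort must contain at least two centers")
  n <- nrow(cohort)
  n_test <- round(test_fraction * n)
  in_center <- cohort$center == test_center
  test_ids <- cohort$id[in_center]
  n_extra <- n_test - length(test_ids)
  if (n_extra < 0)
    stop("test_fraction smaller than the external center itself")
  if (n_extra > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    pool <- cohort$id[!in_center]
    test_ids <- c(test_ids, sample(pool, n_extra))
  }
  train_ids <- setdiff(cohort$id, test_ids)
  list(train_ids = train_ids, test_ids = test_ids,
       meta = list(test_center = test_center, test_fraction = test_fraction,
                   seed = seed, n_train = length(train_ids),
                   n_test = length(test_ids)))
}

#' Stratified k-fold plan
#'
#' Partitions the cohort into `k` folds stratified by class label so every
#' fold sees both classes; fold sizes differ by at most one.
#'
#' @param cohort data.frame with `id` and `label` columns.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return list of `k` character vectors of test ids (disjoint, covering
#'   the cohort).
#' @export
kfold_plan <- function(cohort, k = 10L, seed = 1L) {
  n <- nrow(cohort)
  if (k > n) stop("k exceeds the number of samples")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  folds <- vector("list", k)
  for (cls in unique(cohort$label)) {
    ids <- sample(cohort$id[cohort$label == cls])
    assign_to <- rep(seq_len(k), length.out = length(ids))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], ids[assign_to == f])
    }
  }
  folds
}

#' Confusion matrix from labels and predictions
#'
#' @param truth 0/1 (or patient/control) true labels; patient = positive.
#' @param pred 0/1 predicted labels.
#' @return list with integer `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_matrix <- function(truth, pred) {
  y <- as_binary_labels(truth)
  p <- as_binary_labels(pred)
  list(tp = sum(y == 1 & p == 1), fn = sum(y == 1 & p == 0),
       tn = sum(y == 0 & p == 0), fp = sum(y == 0 & p == 1))
}

#' Diagnostic metrics of a confusion matrix
#'
#' Accuracy, sensitivity, specificity, PPV and NPV are returned as
#' percentages (0-100); F1 in `[0, 1]`; Matthews correlation coefficient in
#' `[-1, 1]`. A zero denominator yields `NaN` with a warning.
#'
#' @param cm list with `tp`, `fn`, `tn`, `fp` (see [confusion_matrix()]).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (percent), `f1`, `mcc`.
#' @export
compute_metrics <- function(cm) {
  with(cm, {
    if (any(c(tp, fn, tn, fp) < 0)) stop("negative confusion-matrix counts")
    n <- tp + fn + tn + fp
    if (n == 0) stop("empty confusion matrix")
    safe <- function(num, den, what) {
      if (den == 0) {
        warning("zero denominator for ", what, "; returning NaN")
        return(NaN)
      }
      num / den
    }
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    c(accuracy = 100 * (tp + tn) / n,
      sensitivity = 100 * safe(tp, tp + fn, "sensitivity"),
      specificity = 100 * safe(tn, tn + fp, "specificity"),
      ppv = 100 * safe(tp, tp + fp, "PPV"),
      npv = 100 * safe(tn, tn + fn, "NPV"),
      f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"),
      mcc = if (mcc_den == 0) {
        warning("zero denominator for MCC; returning NaN")
        NaN
      } else (tp * tn - fp * fn) / mcc_den)
  })
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with midranks for ties, equivalent to the area
#' under the empirical ROC curve.
#'
#' @param truth 0/1 (or patient/control) labels; both classes required.
#' @param scores numeric scores for the positive (patient) class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, scores) {
  y <- as_binary_labels(truth)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for a metric
#'
#' Percentile 2.5/97.5% bounds over seeded class-stratified resamples.
#' Resamples on which the metric is undefined (e.g. an empty predicted
#' positive class) are skipped and counted.
#'
#' @param truth 0/1 labels.
#' @param x per-sample predictions or scores paired with `truth`.
#' @param metric function `(truth, x) -> scalar`, e.g.
#'   `function(y, p) compute_metrics(confusion_matrix(y, p))["accuracy"]`
#'   or [roc_auc()].
#' @param reps bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @return Named vector `lo`, `hi`, with attributes `n_skipped` and
#'   `estimate`.
#' @export
bootstrap_ci <- function(truth, x, metric, reps = 2000L, seed = 1L) {
  y <- as_binary_labels(truth)
  n <- length(y)
  if (n < 10) stop("bootstrap requires n >= 10")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  by_class <- split(seq_len(n), y)
  vals <- numeric(reps)
  skipped <- 0L
  for (b in seq_len(reps)) {
    idx <- unlist(lapply(by_class, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    v <- suppressWarnings(tryCatch(metric(y[idx], x[idx]),
                                   error = function(e) NaN))
    if (!is.finite(v)) {
      skipped <- skipped + 1L
      vals[b] <- NA_real_
    } else vals[b] <- v
  }
  est <- suppressWarnings(metric(y, x))
  ci <- stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(c(lo = ci[1], hi = ci[2]), n_skipped = skipped, estimate = est)
}

#' Integer confusion matrix from printed rates
#'
#' Recovers the confusion matrix behind published sensitivity/specificity
#' percentages at known class sizes: TP minimizes
#' `|100 * TP / n_pos - sens_pct|` (ties toward larger TP), TN likewise.
#'
#' @param n_pos,n_neg class sizes.
#' @param sens_pct,spec_pct printed sensitivity and specificity in percent.
#' @return list `tp`, `fn`, `tn`, `fp` (see [confusion_matrix()]).
#' @export
reconstruct_matrix_from_rates <- function(n_pos, n_neg, sens_pct, spec_pct) {
  if (sens_pct < 0 || sens_pct > 100 || spec_pct < 0 || spec_pct > 100)
    stop("rates must lie in [0, 100]")
  pick <- function(nn, pct) {
    cand <- 0:nn
    err <- abs(100 * cand / nn - pct)
    best <- cand[err == min(err)]
    max(best)  # tie toward the larger count
  }
  tp <- pick(n_pos, sens_pct)
  tn <- pick(n_neg, spec_pct)
  list(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' Full metrics report for a labelled score set
#'
#' Bundles the confusion matrix at threshold 0.5, all Table-style metrics,
#' the AUC, and (optionally) bootstrap CIs per metric.
#'
#' @param truth 0/1 or patient/control labels.
#' @param prob_patient per-sample probability of the patient class.
#' @param ci if `TRUE`, attach 95% stratified bootstrap CIs.
#' @param reps,seed bootstrap parameters.
#' @param protocol free-text tag stored in the report.
#' @return list with `confusion`, `metrics` (named vector incl. `auc` as
#'   percent), optional `ci` (list of lo/hi pairs), `protocol`, `n`.
#' @export
metrics_report <- function(truth, prob_patient, ci = FALSE, reps = 2000L,
                           seed = 1L, protocol = "test") {
  pred <- as.integer(prob_patient >= 0.5)
  cm <- confusion_matrix(truth, pred)
  met <- c(compute_metrics(cm), auc = 100 * roc_auc(truth, prob_patient))
  out <- list(confusion = cm, metrics = met, protocol = protocol,
              n = length(truth))
  if (ci) {
    mk <- function(fun) bootstrap_ci(truth, prob_patient, fun, reps, seed)
    thr <- function(name) function(y, s) {
      compute_metrics(confusion_matrix(y, as.integer(s >= 0.5)))[[name]]
    }
    out$ci <- list(
      accuracy = mk(thr("accuracy")), sensitivity = mk(thr("sensitivity")),
      specificity = mk(thr("specificity")), ppv = mk(thr("ppv")),
      npv = mk(thr("npv")), f1 = mk(thr("f1")), mcc = mk(thr("mcc")),
      auc = mk(function(y, s) 100 * roc_auc(y, s)))
  }
  out
}
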