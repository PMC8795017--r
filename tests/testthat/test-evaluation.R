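table1_cohort <- function() {
  # cohort shaped like the four-center study: 260 ears, 24 at center D
  counts <- list(A = c(48, 23), B = c(33, 24), C = c(33, 75), D = c(6, 18))
  rows <- do.call(rbind, lapply(names(counts), function(cn) {
    data.frame(center = cn,
               label = rep(c("patient", "control"), counts[[cn]]),
               stringsAsFactors = FALSE)
  }))
  rows$id <- sprintf("e%03d", seq_len(nrow(rows)))
  rows
}

test_that("center-aware 74/26 split reproduces the study sizes", {
  co <- table1_cohort()
  sp <- make_split(co, test_center = "D", test_fraction = 0.26, seed = 1)
  expect_length(sp$train_ids, 192)
  expect_length(sp$test_ids, 68)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  d_ids <- co$id[co$center == "D"]
  expect_true(all(d_ids %in% sp$test_ids))
  # different seeds change only the non-D complement
  sp2 <- make_split(co, "D", 0.26, seed = 2)
  expect_true(all(d_ids %in% sp2$test_ids))
  expect_false(setequal(sp$test_ids, sp2$test_ids))
  # a fraction that covers only center D gives exactly center D
  sp3 <- make_split(co, "D", 24 / 260, seed = 1)
  expect_setequal(sp3$test_ids, d_ids)
  expect_error(make_split(co, "Z"), "not present")
})

test_that("stratified k-fold partitions evenly", {
  co <- table1_cohort()
  folds <- kfold_plan(co, k = 10, seed = 3)
  expect_length(folds, 10)
  sizes <- lengths(folds)
  expect_true(all(sizes == 26))
  expect_setequal(unlist(folds), co$id)
  expect_equal(sum(lengths(folds)), 260)  # pairwise disjoint given setequal
  for (f in folds) {
    labs <- co$label[match(f, co$id)]
    expect_setequal(unique(labs), c("patient", "control"))
  }
  # leave-one-out limit
  small <- co[1:12, ]
  loo <- kfold_plan(small, k = 12, seed = 1)
  expect_true(all(lengths(loo) == 1))
  expect_error(kfold_plan(small, k = 13), "exceeds")
})

test_that("published-table worked examples are reproduced", {
  tr <- reconstruct_matrix_from_rates(96, 96, 80.2, 65.6)
  expect_equal(tr, list(tp = 77, fn = 19, tn = 63, fp = 33))
  m <- compute_metrics(tr)
  expect_equal(round(m[["accuracy"]], 1), 72.9)
  expect_equal(round(m[["ppv"]], 1), 70.0)
  expect_equal(round(m[["npv"]], 1), 76.8)
  expect_equal(round(m[["f1"]], 2), 0.75)
  expect_equal(round(m[["mcc"]], 2), 0.46)

  te <- reconstruct_matrix_from_rates(24, 44, 83.4, 81.8)
  expect_equal(te, list(tp = 20, fn = 4, tn = 36, fp = 8))
  mt <- compute_metrics(te)
  # 56/68 = 82.35%: agrees with the printed 82.3 to its precision
  expect_lt(abs(mt[["accuracy"]] - 82.3), 0.06)
  expect_equal(round(mt[["npv"]], 1), 90.0)
  expect_equal(round(mt[["f1"]], 2), 0.77)
  expect_equal(round(mt[["mcc"]], 2), 0.63)

  perfect <- reconstruct_matrix_from_rates(10, 10, 100, 100)
  expect_equal(perfect, list(tp = 10, fn = 0, tn = 10, fp = 0))
  mp <- compute_metrics(perfect)
  expect_equal(mp[["accuracy"]], 100)
  expect_equal(mp[["mcc"]], 1)
})

test_that("metrics agree with textbook formulas on random matrices", {
  set.seed(30)
  for (rep in 1:200) {
    cm <- list(tp = sample(0:40, 1), fn = sample(0:40, 1),
               tn = sample(0:40, 1), fp = sample(0:40, 1))
    if (sum(unlist(cm)) == 0) next
    m <- suppressWarnings(compute_metrics(cm))
    with(cm, {
      expect_equal(m[["accuracy"]], 100 * (tp + tn) / (tp + tn + fp + fn))
      if (tp + fn > 0) expect_equal(m[["sensitivity"]],
                                    100 * tp / (tp + fn))
      if (tn + fp > 0) expect_equal(m[["specificity"]],
                                    100 * tn / (tn + fp))
      if (2 * tp + fp + fn > 0)
        expect_equal(m[["f1"]], 2 * tp / (2 * tp + fp + fn))
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den > 0)
        expect_equal(m[["mcc"]], (tp * tn - fp * fn) / sqrt(den))
      if (is.finite(m[["mcc"]])) {
        expect_gte(m[["mcc"]], -1)
        expect_lte(m[["mcc"]], 1)
      }
    })
  }
  # an empty positive class warns for sensitivity and for MCC
  expect_warning(
    expect_warning(compute_metrics(list(tp = 0, fn = 0, tn = 3, fp = 2)),
                   "sensitivity"),
    "MCC")
  expect_error(compute_metrics(list(tp = -1, fn = 1, tn = 1, fp = 1)),
               "negative")
})

test_that("rank-based AUC handles hand cases, ties and monotone transforms", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(roc_auc(c(1, 0), c(2, 2)), 0.5)  # midrank tie handling
  set.seed(31)
  y <- rep(0:1, 50)
  s <- rnorm(100) + y
  expect_equal(roc_auc(y, s), roc_auc(y, exp(s)), tolerance = 1e-12)
  expect_equal(roc_auc(y, s), roc_auc(y, 2 * s - 7), tolerance = 1e-12)
  # chance level under independence
  s0 <- rnorm(2000)
  y0 <- rep(0:1, 1000)
  expect_lt(abs(roc_auc(y0, s0) - 0.5), 0.05)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  y <- rep(0:1, 30)
  s <- rnorm(60) + 0.8 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-10)
})

test_that("bootstrap confidence intervals behave sanely", {
  y <- rep(c(1, 0), 25)
  acc_metric <- function(yy, pp)
    compute_metrics(confusion_matrix(yy, pp))[["accuracy"]]
  # constant correct predictions: CI collapses
  ci <- bootstrap_ci(y, y, acc_metric, reps = 200, seed = 1)
  expect_equal(as.numeric(ci), c(100, 100))
  # point estimate inside the interval
  set.seed(33)
  p <- ifelse(stats::runif(50) < 0.8, y, 1 - y)
  ci2 <- bootstrap_ci(y, p, acc_metric, reps = 500, seed = 2)
  est <- attr(ci2, "estimate")
  expect_gte(est, ci2[["lo"]])
  expect_lte(est, ci2[["hi"]])
  # width shrinks roughly like 1/sqrt(n)
  width <- function(n, seed) {
    set.seed(seed)
    yy <- rep(0:1, n / 2)
    pp <- ifelse(stats::runif(n) < 0.75, yy, 1 - yy)
    ci <- bootstrap_ci(yy, pp, acc_metric, reps = 400, seed = seed)
    ci[["hi"]] - ci[["lo"]]
  }
  w <- vapply(c(50, 200, 800), width, numeric(1), seed = 5)
  expect_true(w[1] > w[2] && w[2] > w[3])
  expect_lt(w[3] / w[1], 0.5)
})
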