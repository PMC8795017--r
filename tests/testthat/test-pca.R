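make_lowrank <- function(n = 60, p = 50, k = 10, noise = 0.01, seed = 1) {
  set.seed(seed)
  sig <- matrix(rnorm(n * k), n, k)
  X <- sig %*% matrix(rnorm(k * p), k, p) + matrix(rnorm(n * p, sd = noise),
                                                   n, p)
  colnames(X) <- paste0("f", seq_len(p))
  X
}

test_that("ten components capture planted ten-dimensional structure", {
  X <- make_lowrank()
  fit <- fit_pca(X, 10)
  z <- labradiomics:::standardize_features(X, fit$standardizer)
  total <- sum(apply(z, 2, var))
  expect_gte(sum(fit$model$explained_variance) / total, 0.95)
  expect_true(all(diff(fit$model$explained_variance) <= 1e-9))
  # orthonormal loadings
  L <- fit$model$loadings
  expect_equal(unname(crossprod(L)), diag(10), tolerance = 1e-9)
})

test_that("transform reproduces PCA score properties", {
  X <- make_lowrank(n = 40)
  fit <- fit_pca(X, 10)
  sc <- pca_transform(X, fit)
  cv <- cov(sc)
  expect_equal(unname(diag(cv)), unname(fit$model$explained_variance),
               tolerance = 1e-8)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  # a row at the training mean maps to the zero score
  at_mean <- matrix(fit$standardizer$mean, 1,
                    dimnames = list(NULL, colnames(X)))
  expect_lt(max(abs(pca_transform(at_mean, fit))), 1e-10)
  # inverse transform is a right inverse on scores
  expect_equal(pca_inverse_transform(sc, fit) %*% fit$model$loadings, sc,
               tolerance = 1e-8)
  expect_error(pca_transform(X[, 1:10], fit), "mismatch")
})

test_that("full-rank retention reconstructs the data exactly", {
  X <- make_lowrank(n = 12, p = 8, k = 8, noise = 1)
  fit <- fit_pca(X, 8)
  z <- labradiomics:::standardize_features(X, fit$standardizer)
  recon <- pca_inverse_transform(pca_transform(X, fit), fit)
  expect_equal(unname(recon), unname(z), tolerance = 1e-8)
})

test_that("duplicating every row changes variances only by a scale", {
  X <- make_lowrank(n = 30)
  f1 <- fit_pca(X, 5)
  f2 <- fit_pca(rbind(X, X), 5)
  agree <- abs(colSums(f1$model$loadings * f2$model$loadings))
  expect_equal(unname(agree), rep(1, 5), tolerance = 1e-6)
  # population covariance is unchanged; only the n/(n-1) factor moves
  expect_equal(f2$model$explained_variance / f1$model$explained_variance,
               rep((60 / 59) * (29 / 30), 5), tolerance = 1e-6)
})

test_that("guard conditions are enforced", {
  X <- make_lowrank(n = 8, p = 20)
  expect_error(fit_pca(X, 10), "fewer rows")
  X2 <- make_lowrank(n = 20, p = 10, k = 5)
  X2[3, 4] <- NA
  expect_error(fit_pca(X2, 5), "non-finite")
})

test_that("contribution scores follow the mean-|loading| rule", {
  # hand-checkable loadings on three features, two components
  L <- cbind(c(1, 0, 0.5), c(0, 1, 0.5))
  L <- apply(L, 2, function(v) v / sqrt(sum(v^2)))
  rownames(L) <- c("a", "b", "c")
  fit <- list(model = list(loadings = L))
  rep_ <- feature_contributions(fit, threshold = 0.7)
  raw <- rowMeans(abs(L))
  expect_equal(rep_$contribution, unname(raw / max(raw)))
  expect_equal(max(rep_$contribution), 1)
  expect_identical(rep_$selected, rep_$contribution > 0.7)
  # symmetric features get identical scores; permutation permutes scores
  X <- make_lowrank(n = 30, p = 12, k = 3)
  fit1 <- fit_pca(X, 3)
  perm <- sample(ncol(X))
  fit2 <- fit_pca(X[, perm], 3)
  c1 <- feature_contributions(fit1)
  c2 <- feature_contributions(fit2)
  expect_equal(c2$contribution[match(c1$feature, c2$feature)],
               c1$contribution, tolerance = 1e-9)
})

test_that("a planted discriminative feature group tops the contributions", {
  # The mean-|loading| score rewards features that dominate the retained
  # components; a single strongly correlated block forms the leading
  # component, so with few retained components it must rank on top.
  set.seed(6)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 40, sd = 0.5), n, 40)
  X[, 1:5] <- X[, 1:5] + 4 * y  # dominant correlated block
  colnames(X) <- paste0("f", 1:40)
  fit <- fit_pca(X, 2)
  ct <- feature_contributions(fit)
  top5 <- ct$feature[order(-ct$contribution)][1:5]
  expect_setequal(top5, paste0("f", 1:5))
})
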