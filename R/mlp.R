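#' Multi-layer perceptron configuration
#'
#' One hidden layer of 500 ReLU units, a 2-unit softmax output
#' (control = 0, patient = 1), seeded mini-batch Adam at learning rate
#' 0.001, and early stopping on an internal stratified validation split carved from
#' the training data (never the test set).
#'
#' @param hidden_units hidden layer width.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (capped at the training-set size).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement before halting; best-epoch weights are restored).
#' @param min_epochs warm-up: epochs trained before early stopping arms and
#'   best-epoch tracking starts, so a noisy early plateau of the small
#'   validation loss cannot freeze an underfit model.
#' @param validation_fraction fraction of training rows held out internally
#'   for early stopping, stratified by class.
#' @param seed RNG seed controlling initialization and the validation split.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(hidden_units = 500L, learning_rate = 0.001,
                       batch_size = 32L, max_epochs = 1000L, patience = 20L,
                       min_epochs = 100L, validation_fraction = 0.1,
                       seed = 1L) {
  if (hidden_units < 1) stop("hidden_units must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

mlp_forward <- function(w, x) {
  h <- sweep(x %*% w$W1, 2, w$b1, `+`)
  h[h < 0] <- 0
  logits <- sweep(h %*% w$W2, 2, w$b2, `+`)
  pm <- logits - apply(logits, 1, max)
  e <- exp(pm)
  probs <- e / rowSums(e)
  list(h = h, probs = probs)
}

mlp_loss <- function(probs, y01) {
  # mean cross-entropy; y01 is the 0/1 class vector
  idx <- cbind(seq_along(y01), y01 + 1L)
  -mean(log(pmax(probs[idx], 1e-12)))
}

#' Train the MLP classifier on PC scores
#'
#' Minimizes mean cross-entropy with mini-batch Adam (seeded shuffling, so
#' training is fully deterministic). Training halts when
#' the internal validation loss has not improved for `patience` epochs; the
#' weights of the best validation epoch are restored. Deterministic given
#' the config seed.
#'
#' @param scores numeric matrix (n x d) of inputs (principal-component
#'   scores).
#' @param labels vector with two classes; `"patient"`/1 is the positive
#'   class, anything else negative, or a 0/1 numeric vector.
#' @param config an [mlp_config()].
#' @return An `mlp_model`: weights, training history (`train_loss`,
#'   `val_loss` per epoch), `stop_epoch`, `best_epoch`.
#' @export
mlp_train <- function(scores, labels, config = mlp_config()) {
  x <- as.matrix(scores)
  if (any(!is.finite(x))) stop("non-finite inputs")
  y01 <- as_binary_labels(labels)
  if (length(unique(y01)) < 2) stop("training labels contain a single class")
  if (min(table(y01)) < 2) stop("need >= 2 samples per class")
  n <- nrow(x)
  d <- ncol(x)
  H <- config$hidden_units

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  # stratified internal validation split
  val <- unlist(lapply(split(seq_len(n), y01), function(ix) {
    nv <- max(1L, round(length(ix) * config$validation_fraction))
    sample(ix, nv)
  }), use.names = FALSE)
  tr <- setdiff(seq_len(n), val)

  w <- list(W1 = matrix(stats::rnorm(d * H, 0, sqrt(2 / d)), d, H),
            b1 = numeric(H),
            W2 = matrix(stats::rnorm(H * 2, 0, sqrt(1 / H)), H, 2),
            b2 = numeric(2))
  mom <- lapply(w, function(p) p * 0)
  vel <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate

  xtr <- x[tr, , drop = FALSE]; ytr <- y01[tr]
  xva <- x[val, , drop = FALSE]; yva <- y01[val]
  ntr <- length(tr)
  Ttr <- cbind(1 - ytr, ytr)  # one-hot targets

  best <- list(loss = Inf, epoch = 0L, w = w)
  hist_tr <- numeric(0)
  hist_va <- numeric(0)
  wait <- 0L
  bs <- min(config$batch_size, ntr)
  adam_t <- 0

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(ntr)
    starts <- seq(1, ntr, by = bs)
    for (s in starts) {
      bi <- perm[s:min(s + bs - 1L, ntr)]
      xb <- xtr[bi, , drop = FALSE]
      Tb <- Ttr[bi, , drop = FALSE]
      fw <- mlp_forward(w, xb)
      # gradients of mean cross-entropy through softmax
      dlogits <- (fw$probs - Tb) / length(bi)
      gW2 <- t(fw$h) %*% dlogits
      gb2 <- colSums(dlogits)
      dh <- dlogits %*% t(w$W2)
      dh[fw$h <= 0] <- 0
      grads <- list(W1 = t(xb) %*% dh, b1 = colSums(dh), W2 = gW2, b2 = gb2)
      adam_t <- adam_t + 1
      for (nm in names(w)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * grads[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^adam_t)
        vhat <- vel[[nm]] / (1 - b2^adam_t)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }

    hist_tr[epoch] <- mlp_loss(mlp_forward(w, xtr)$probs, ytr)
    vloss <- mlp_loss(mlp_forward(w, xva)$probs, yva)
    hist_va[epoch] <- vloss
    if (epoch < config$min_epochs) next
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, epoch = epoch, w = w)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  if (best$epoch == 0L) {  # max_epochs < min_epochs: keep final weights
    best <- list(loss = hist_va[length(hist_va)], epoch = length(hist_va),
                 w = w)
  }
  structure(list(weights = best$w, config = config,
                 history = list(train_loss = hist_tr, val_loss = hist_va),
                 best_epoch = best$epoch, stop_epoch = length(hist_va)),
            class = "mlp_model")
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(labels %in% c("patient", "1", "MD", "case"))
}

#' Class probabilities from a trained MLP
#'
#' @param model an `mlp_model` from [mlp_train()].
#' @param scores input matrix with the model's input dimensionality.
#' @return Matrix (n x 2) of softmax probabilities, columns
#'   `control`/`patient`; rows sum to 1. Attribute `"class"` holds the
#'   0/1 argmax labels (probability of the patient class >= 0.5 -> 1).
#' @export
mlp_predict_proba <- function(model, scores) {
  x <- as.matrix(scores)
  if (ncol(x) != nrow(model$weights$W1)) stop("input dimension mismatch")
  probs <- mlp_forward(model$weights, x)$probs
  colnames(probs) <- c("control", "patient")
  attr(probs, "class_pred") <- as.integer(probs[, 2] >= 0.5)
  probs
}
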