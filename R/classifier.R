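# A small convolutional sequence classifier: two valid-mode convolution +
# ReLU + max-pool blocks followed by a dense sigmoid read-out, trained with
# Adam on binary cross-entropy. Implemented directly on matrix algebra
# (im2col gathers + BLAS products), which keeps training deterministic for a
# fixed seed and makes every intermediate available to the attribution
# back-ends.

#' Configuration for the enhancer classifier
#'
#' @param window_length input window length L in bp.
#' @param n_filters integer vector of length 2, filters per conv layer.
#' @param filter_widths integer vector of length 2, conv kernel widths.
#' @param pool_widths integer vector of length 2, non-overlapping max-pool
#'   widths (stride = width; trailing remainder positions are dropped). A
#'   width of 0, or one at least as large as the layer, pools globally; the
#'   default global second pool makes the read-out translation-invariant,
#'   so the network must rely on motif-like filters rather than positions.
#' @param rc_equivariant pair every first-layer filter with a weight-tied
#'   reverse-complement copy (default FALSE; strand handling is done at
#'   interpretation time by scoring both strands and taking the absolute
#'   maximum, and the untied filter bank gave markedly better attribution
#'   of non-palindromic motifs in development benchmarks).
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 weight decay applied at each step.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience: training stops after this many
#'   epochs without a validation-auROC improvement.
#' @param seed integer seed controlling initialisation and shuffling.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(window_length = 300L, n_filters = c(32L, 32L),
                              filter_widths = c(12L, 4L), pool_widths = c(8L, 0L),
                              rc_equivariant = FALSE,
                              learning_rate = 5e-3, weight_decay = 1e-4,
                              batch_size = 16L,
                              epochs = 50L, patience = 5L, seed = 1L) {
  stopifnot(length(n_filters) == 2L, length(filter_widths) == 2L,
            length(pool_widths) == 2L, window_length > 0, learning_rate > 0,
            weight_decay >= 0, batch_size > 0, epochs > 0, patience > 0)
  cfg <- list(window_length = as.integer(window_length),
              n_filters = as.integer(n_filters),
              filter_widths = as.integer(filter_widths),
              pool_widths = as.integer(pool_widths),
              rc_equivariant = isTRUE(rc_equivariant),
              learning_rate = learning_rate, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), patience = as.integer(patience),
              seed = as.integer(seed))
  d <- cnn_dims(cfg) # validates that the architecture fits the window
  if (d$flat <= 0) stop("window too short for the configured architecture")
  structure(cfg, class = "classifier_config")
}

cnn_dims <- function(cfg) {
  L <- cfg$window_length
  w1 <- cfg$filter_widths[1]; w2 <- cfg$filter_widths[2]
  F1 <- cfg$n_filters[1]; F2 <- cfg$n_filters[2]
  p1 <- cfg$pool_widths[1]; p2 <- cfg$pool_widths[2]
  rc <- isTRUE(cfg$rc_equivariant)
  C1 <- if (rc) 2L * F1 else F1 # channels after conv1 (+ RC copies)
  n1 <- L - w1 + 1L
  if (p1 <= 0L || p1 > n1) p1 <- n1 # global pool
  n1p <- n1 %/% p1
  n2 <- n1p - w2 + 1L
  if (p2 <= 0L || p2 > n2) p2 <- max(n2, 1L)
  n2p <- n2 %/% p2
  list(L = L, w1 = w1, w2 = w2, F1 = F1, F2 = F2, C1 = C1, rc = rc,
       p1 = p1, p2 = p2, n1 = n1, n1p = n1p, n2 = n2, n2p = n2p,
       flat = n2p * F2)
}

# Column permutation mapping a (width x 4)-flattened filter to its reverse
# complement: position order flipped, channels A<->T and C<->G swapped.
rc_filter_perm <- function(w1) {
  comp <- c(4L, 3L, 2L, 1L)
  perm <- integer(4L * w1)
  for (b in 1:4) for (k in seq_len(w1)) {
    perm[k + w1 * (b - 1L)] <- (w1 + 1L - k) + w1 * (comp[b] - 1L)
  }
  perm
}

# Effective first-layer filter bank (free filters + tied RC copies).
conv1_bank <- function(params, d) {
  if (d$rc) {
    list(W = cbind(params$W1, params$W1[rc_filter_perm(d$w1), , drop = FALSE]),
         b = c(params$b1, params$b1))
  } else {
    list(W = params$W1, b = params$b1)
  }
}

# im2col index matrices into the column-major flattening of the layer input.
cnn_indices <- function(d) {
  idx1 <- matrix(0L, d$n1, 4L * d$w1)
  for (b in 1:4) for (k in seq_len(d$w1)) {
    idx1[, k + d$w1 * (b - 1L)] <- seq_len(d$n1) + (k - 1L) + d$L * (b - 1L)
  }
  idx2 <- matrix(0L, d$n2, d$C1 * d$w2)
  for (f in seq_len(d$C1)) for (k in seq_len(d$w2)) {
    idx2[, k + d$w2 * (f - 1L)] <- seq_len(d$n2) + (k - 1L) + d$n1p * (f - 1L)
  }
  list(idx1 = idx1, idx2 = idx2)
}

cnn_init_params <- function(cfg, d) {
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  list(W1 = he(4 * d$w1, 4L * d$w1, d$F1), b1 = numeric(d$F1),
       W2 = he(d$w2 * d$C1, d$w2 * d$C1, d$F2), b2 = numeric(d$F2),
       Wd = stats::rnorm(d$flat, 0, sqrt(1 / d$flat)), bd = 0)
}

# Non-overlapping max-pool over the row (position) dimension of an
# n x F activation matrix; returns pooled values and in-window argmax.
pool_max <- function(A, pool, npool, F) {
  a <- A[seq_len(pool * npool), , drop = FALSE]
  dim(a) <- c(pool, npool, F)
  P <- a[1L, , , drop = TRUE]
  if (npool == 1L || F == 1L) P <- matrix(P, npool, F)
  I <- matrix(1L, npool, F)
  if (pool > 1L) for (k in 2:pool) {
    ak <- a[k, , , drop = TRUE]
    if (npool == 1L || F == 1L) ak <- matrix(ak, npool, F)
    upd <- ak > P
    I[upd] <- k
    P[upd] <- ak[upd]
  }
  list(P = P, I = I)
}

# Scatter pooled-level values back to pre-pool rows at the recorded argmax.
unpool <- function(V, I, pool, n, F) {
  out <- matrix(0, n, F)
  rows <- (row(I) - 1L) * pool + I
  out[cbind(as.vector(rows), as.vector(col(I)))] <- as.vector(V)
  out
}

# Full forward pass on one encoded window (xf = column-major L x 4 vector).
cnn_forward <- function(params, xf, d, ix) {
  bank <- conv1_bank(params, d)
  X1 <- matrix(xf[ix$idx1], d$n1, 4L * d$w1)
  Z1 <- X1 %*% bank$W
  Z1 <- Z1 + rep(bank$b, each = d$n1)
  A1 <- Z1 * (Z1 > 0)
  pl1 <- pool_max(A1, d$p1, d$n1p, d$C1)
  X2 <- matrix(as.vector(pl1$P)[ix$idx2], d$n2, d$w2 * d$C1)
  Z2 <- X2 %*% params$W2
  Z2 <- Z2 + rep(params$b2, each = d$n2)
  A2 <- Z2 * (Z2 > 0)
  pl2 <- pool_max(A2, d$p2, d$n2p, d$F2)
  h <- as.vector(pl2$P)
  z <- sum(h * params$Wd) + params$bd
  list(xf = xf, X1 = X1, Z1 = Z1, A1 = A1, P1 = pl1$P, I1 = pl1$I,
       X2 = X2, Z2 = Z2, A2 = A2, P2 = pl2$P, I2 = pl2$I,
       h = h, z = z, p = 1 / (1 + exp(-z)))
}

# Scatter-add column-major values into a flat vector of length n.
scatter_add <- function(values, index, n) {
  out <- numeric(n)
  rs <- rowsum(as.vector(values), as.vector(index))
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

# Gradients of BCE loss wrt parameters for one example (dz = p - y).
cnn_backward <- function(params, fw, dz, d, ix) {
  dWd <- fw$h * dz
  dh <- params$Wd * dz
  dA2 <- unpool(matrix(dh, d$n2p, d$F2), fw$I2, d$p2, d$n2, d$F2)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$X2, dZ2)
  db2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(params$W2)
  dP1 <- matrix(scatter_add(dX2, ix$idx2, d$n1p * d$C1), d$n1p, d$C1)
  dA1 <- unpool(dP1, fw$I1, d$p1, d$n1, d$C1)
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1full <- crossprod(fw$X1, dZ1)
  db1full <- colSums(dZ1)
  if (d$rc) { # fold the tied RC copies' gradient back onto the free filters
    perm <- rc_filter_perm(d$w1)
    rc_cols <- d$F1 + seq_len(d$F1)
    dW1 <- dW1full[, seq_len(d$F1), drop = FALSE] +
      dW1full[perm, rc_cols, drop = FALSE]
    db1 <- db1full[seq_len(d$F1)] + db1full[rc_cols]
  } else {
    dW1 <- dW1full
    db1 <- db1full
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wd = dWd, bd = dz)
}

adam_step <- function(params, grads, state, lr, t, wd = 0) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    decay <- if (nm %in% c("W1", "W2", "Wd")) lr * wd * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) - decay
  }
  list(params = params, state = state)
}

encode_batch <- function(sequences, L) {
  if (any(nchar(sequences) != L)) {
    stop("all sequences must have length ", L)
  }
  lapply(sequences, function(s) as.vector(encode_onehot(s)))
}

#' Train the enhancer classifier
#'
#' Minimises binary cross-entropy with Adam and returns the parameter set
#' with the best validation auROC seen across epochs (early stopping on the
#' configured patience). Reproducible for a fixed seed and thread count.
#'
#' @param train_examples,validation_examples data.frames with `sequence` and
#'   `label` columns (labels 0/1; both classes must be present in each).
#' @param config a [classifier_config()].
#' @param verbose print one line per epoch.
#' @return an object of class `enhancer_cnn` with elements `params`,
#'   `config`, `history` (epoch, train_loss, val_auroc), `best_epoch`.
#' @export
train_classifier <- function(train_examples, validation_examples, config,
                             verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  if (nrow(train_examples) == 0L || nrow(validation_examples) == 0L) {
    stop("train and validation sets must be non-empty")
  }
  if (length(unique(train_examples$label)) < 2L) {
    stop("training set must contain both classes")
  }
  if (length(unique(validation_examples$label)) < 2L) {
    stop("validation set must contain both classes")
  }
  d <- cnn_dims(config)
  ix <- cnn_indices(d)
  xtr <- encode_batch(train_examples$sequence, d$L)
  ytr <- as.numeric(train_examples$label)
  xva <- encode_batch(validation_examples$sequence, d$L)
  yva <- as.numeric(validation_examples$label)
  n <- length(xtr)

  with_seed(config$seed, {
    params <- cnn_init_params(config, d)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    best <- list(auroc = -Inf, params = params, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_auroc = numeric(0))
    tstep <- 0L
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        grads <- lapply(params, function(p) p * 0)
        for (i in bs) {
          fw <- cnn_forward(params, xtr[[i]], d, ix)
          pr <- min(max(fw$p, 1e-12), 1 - 1e-12)
          loss_sum <- loss_sum - (ytr[i] * log(pr) + (1 - ytr[i]) * log(1 - pr))
          g <- cnn_backward(params, fw, fw$p - ytr[i], d, ix)
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
        grads <- lapply(grads, function(g) g / length(bs))
        tstep <- tstep + 1L
        st <- adam_step(params, grads, state, config$learning_rate, tstep,
                        config$weight_decay)
        params <- st$params
        state <- st$state
      }
      pva <- vapply(xva, function(x) cnn_forward(params, x, d, ix)$p, numeric(1))
      va <- auroc(pva, yva)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = loss_sum / n,
                                           val_auroc = va))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val auROC %.4f",
                        epoch, loss_sum / n, va))
      }
      if (va > best$auroc) {
        best <- list(auroc = va, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    structure(list(params = best$params, config = config, dims = d,
                   history = history, best_epoch = best$epoch,
                   best_val_auroc = best$auroc),
              class = "enhancer_cnn")
  })
}

#' Predict enhancer probabilities
#'
#' @param object an `enhancer_cnn` from [train_classifier()].
#' @param sequences character vector of windows of the model's length.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`, one per sequence.
#' @export
predict.enhancer_cnn <- function(object, sequences, ...) {
  d <- object$dims
  ix <- cnn_indices(d)
  xs <- encode_batch(sequences, d$L)
  vapply(xs, function(x) cnn_forward(object$params, x, d, ix)$p, numeric(1))
}

#' @export
print.enhancer_cnn <- function(x, ...) {
  cat(sprintf(paste0("enhancer_cnn: L=%d, conv %dx%d -> pool %d -> conv %dx%d",
                     " -> pool %d -> dense(%d)\n"),
              x$dims$L, x$dims$F1, x$dims$w1, x$dims$p1,
              x$dims$F2, x$dims$w2, x$dims$p2, x$dims$flat))
  cat(sprintf("trained %d epoch(s); best validation auROC %.4f at epoch %d\n",
              nrow(x$history), x$best_val_auroc, x$best_epoch))
  invisible(x)
}

#' Train an ensemble of enhancer classifiers
#'
#' Trains `n_models` classifiers that differ only in their initialisation
#' and shuffling seed (derived deterministically from the configuration
#' seed). Ensemble predictions are the mean member probability and
#' per-nucleotide importance scores are the mean member score, which makes
#' attributions robust to the single-model lottery of which of several
#' co-occurring motifs a network happens to exploit.
#'
#' @inheritParams train_classifier
#' @param n_models ensemble size (default 4).
#' @return an object of class `enhancer_cnn_ensemble` with elements
#'   `members` (list of `enhancer_cnn`), `config`, `n_models`.
#' @export
train_ensemble <- function(train_examples, validation_examples, config,
                           n_models = 4L, verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"), n_models >= 1L)
  members <- lapply(seq_len(n_models), function(k) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, paste0("member", k))
    m <- train_classifier(train_examples, validation_examples, cfg_k)
    if (verbose) {
      message(sprintf("member %d/%d: best val auROC %.4f (epoch %d)",
                      k, n_models, m$best_val_auroc, m$best_epoch))
    }
    m
  })
  structure(list(members = members, config = config,
                 n_models = as.integer(n_models),
                 dims = members[[1]]$dims),
            class = "enhancer_cnn_ensemble")
}

#' @rdname train_ensemble
#' @param object an `enhancer_cnn_ensemble`.
#' @param sequences character vector of windows of the model's length.
#' @param ... unused.
#' @export
predict.enhancer_cnn_ensemble <- function(object, sequences, ...) {
  preds <- vapply(object$members, function(m) predict(m, sequences),
                  numeric(length(sequences)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' @export
print.enhancer_cnn_ensemble <- function(x, ...) {
  cat(sprintf("enhancer_cnn_ensemble of %d members\n", x$n_models))
  for (m in x$members) {
    cat(sprintf("  best val auROC %.4f at epoch %d\n",
                m$best_val_auroc, m$best_epoch))
  }
  invisible(x)
}

#' Area under the ROC curve (rank-based, midrank ties)
#'
#' Equals the probability that a uniformly random positive outranks a
#' uniformly random negative, with ties counted one half.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return auROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auROC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Test-set auROC of a trained classifier
#'
#' @param model an `enhancer_cnn`.
#' @param test_examples data.frame with `sequence` and `label` columns,
#'   both classes present.
#' @return auROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(model, test_examples) {
  if (length(unique(test_examples$label)) < 2L) {
    stop("evaluation requires both classes in the test set")
  }
  auroc(predict(model, test_examples$sequence), test_examples$label)
}
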