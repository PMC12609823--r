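# training engine: AdamW with class-weighted cross-entropy, optional L1,
# duplication+Gaussian-noise augmentation, early stopping and
# plateau-based learning-rate reduction

#' Class weights from training label frequencies
#'
#' `w_c = n_total / (2 * n_c)`, so balanced labels give (1, 1) and the
#' minority class is up-weighted.
#'
#' @param labels integer 0/1 labels.
#' @return numeric weight 2-vector (normal, high).
#' @export
class_weights <- function(labels) {
  if (!length(labels)) stop("no labels")
  n <- length(labels)
  counts <- c(sum(labels == 0), sum(labels == 1))
  if (any(counts == 0)) {
    warning("only one class present; absent class receives weight 0")
    w <- ifelse(counts > 0, n / (2 * counts), 0)
  } else {
    w <- n / (2 * counts)
  }
  w
}

#' Duplication-plus-noise augmentation
#'
#' Returns the original training windows plus `k` noisy copies of each
#' (output size `n * (1 + k)`). Every copy adds zero-mean Gaussian noise
#' whose standard deviation is drawn uniformly from (0, `sd_max`]. Labels
#' and provenance are copied. Only training-tagged sets may be augmented;
#' validation/test sets raise an error.
#'
#' @param ws an `nf_windows` with `split == "train"`.
#' @param k number of additional copies per window.
#' @param sd_max maximum noise standard deviation (on the standardized
#'   scale; default 0.10).
#' @param seed RNG seed.
#' @return augmented `nf_windows`.
#' @export
augment_windows <- function(ws, k, sd_max = 0.10, seed = 1) {
  if (!identical(ws$split, "train"))
    stop("augmentation is restricted to training splits")
  if (k == 0) return(ws)
  n <- n_windows(ws)
  parts <- vector("list", k + 1)
  parts[[1]] <- ws
  with_seed(seed, {
    for (r in seq_len(k)) {
      copy <- ws
      for (i in seq_len(n)) {
        sdev <- runif(1) * sd_max
        if (sdev > 0)
          copy$x[i, , ] <- copy$x[i, , ] + rnorm(length(copy$x[i, , ]), 0, sdev)
      }
      parts[[r + 1]] <- copy
    }
  })
  out <- windows_bind(parts)
  out$split <- "train"
  out$stats <- ws$stats
  out
}

#' Classification loss
#'
#' Class-weighted cross-entropy, averaged with the weights (so uniform
#' logits under balanced weights give `log(2)` per sample), plus an
#' optional L1 penalty `l1 * sum(abs(theta))` over learnable parameters.
#'
#' @param logits n x 2 logit matrix.
#' @param labels integer 0/1 labels.
#' @param weights class weight 2-vector.
#' @param l1 L1 penalty coefficient.
#' @param net optional `nf_net` whose parameters enter the L1 term.
#' @return scalar loss.
#' @export
nf_loss <- function(logits, labels, weights = c(1, 1), l1 = 0, net = NULL) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  p <- softmax_rows(logits)
  py <- ifelse(labels == 1, p[, 2], p[, 1])
  w <- weights[labels + 1]
  loss <- sum(-w * log(pmax(py, 1e-30))) / sum(w)
  if (l1 > 0 && !is.null(net))
    loss <- loss + l1 * sum(abs(nf_net_get_theta(net$ptr)))
  loss
}

#' Training configuration
#'
#' Optimization defaults: AdamW (batch 64, learning rate 1e-3, decoupled
#' weight decay 1e-4), class-weighted cross-entropy, optional L1, up to 100
#' epochs with early stopping (patience 50, monitoring validation loss),
#' learning-rate halving after 10 epochs without validation improvement,
#' and 5 duplication-augmentation copies with noise SD up to 0.10.
#'
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param weight_decay decoupled (AdamW) weight-decay rate.
#' @param l1_lambda L1 penalty coefficient.
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement; 0 stops after the first non-improving epoch).
#' @param lr_factor,lr_patience plateau LR schedule: multiply the learning
#'   rate by `lr_factor` after `lr_patience` epochs without improvement.
#' @param aug_k,aug_sd_max augmentation copies and maximum noise SD.
#' @param max_train_windows optional cap on training windows (stratified
#'   subsample before augmentation) for desk-scale runs; `NULL` = all.
#' @param seed RNG seed (shuffling, augmentation).
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 64, lr = 1e-3, weight_decay = 1e-4,
                         l1_lambda = 0, max_epochs = 100, patience = 50,
                         lr_factor = 0.5, lr_patience = 10, aug_k = 5,
                         aug_sd_max = 0.10, max_train_windows = NULL,
                         seed = 1) {
  if (batch_size < 1) stop("'batch_size' must be >= 1")
  if (lr <= 0) stop("'lr' must be positive")
  if (weight_decay < 0 || l1_lambda < 0 || aug_sd_max < 0)
    stop("rates must be >= 0")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, l1_lambda = l1_lambda,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 aug_k = as.integer(aug_k), aug_sd_max = aug_sd_max,
                 max_train_windows = max_train_windows,
                 seed = as.integer(seed)), class = "train_config")
}

#' Train a network
#'
#' Runs AdamW minibatch training with class-weighted cross-entropy
#' (weights from the training labels) and optional L1. After every epoch
#' the validation loss is evaluated; the learning rate is multiplied by
#' `lr_factor` when it fails to improve for `lr_patience` epochs, training
#' stops after `patience` epochs without improvement (or at `max_epochs`),
#' and the parameters of the best-validation epoch are restored. Fully
#' deterministic given `config$seed`.
#'
#' @param net an `nf_net` (modified in place; also returned in the report).
#' @param train,val `nf_windows` sets; `val = NULL` disables early stopping
#'   and best-epoch restoration.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `nf_train_report`: per-epoch history data.frame
#'   (`epoch`, `lr`, `train_loss`, `val_loss`), `best_epoch`,
#'   `stop_reason`, `weights`, and the trained `net`.
#' @export
train_network <- function(net, train, val = NULL, config = train_config(),
                          verbose = FALSE) {
  if (n_windows(train) == 0) stop("empty training set")
  if (!is.null(val) && n_windows(val) == 0) stop("empty validation set")
  # a single-epoch schedule has nothing to select or stop early, so the
  # validation pass would be dead work (results are unaffected: it draws
  # no random numbers)
  if (!is.null(val) && config$max_epochs == 1) val <- NULL
  w <- class_weights(train$y)
  x <- net_input(net, train)
  y <- as.integer(train$y)
  xval <- if (!is.null(val)) net_input(net, val)
  yval <- if (!is.null(val)) as.integer(val$y)
  n <- length(y)
  lr <- config$lr
  best <- Inf
  best_snap <- NULL
  best_epoch <- 0L
  since_best <- 0L
  since_lr <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tl <- 0
      nb <- 0L
      at <- 1L
      while (at <= n) {
        idx <- ord[at:min(n, at + config$batch_size - 1L)]
        xb <- if (is.matrix(x)) x[idx, , drop = FALSE]
              else x[idx, , , drop = FALSE]
        tl <- tl + nf_net_train_batch(net$ptr, xb, y[idx], w, lr,
                                      config$weight_decay, config$l1_lambda)
        nb <- nb + 1L
        at <- at + config$batch_size
      }
      vl <- NA_real_
      if (!is.null(val))
        vl <- nf_loss(net_logits(net, xval), yval, w)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = tl / nb, val_loss = vl)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        epoch, lr, tl / nb, vl))
      if (!is.null(val)) {
        if (vl < best - 1e-12) {
          best <- vl
          best_epoch <- epoch
          best_snap <- net_get_params(net)
          since_best <- 0L
          since_lr <- 0L
        } else {
          since_best <- since_best + 1L
          since_lr <- since_lr + 1L
          if (since_best > config$patience) {
            stop_reason <- "early_stopping"
            break
          }
          if (since_lr > config$lr_patience) {
            lr <- lr * config$lr_factor
            since_lr <- 0L
          }
        }
      }
    }
  })
  if (!is.null(best_snap)) net_set_params(net, best_snap)
  structure(list(history = do.call(rbind, hist), best_epoch = best_epoch,
                 stop_reason = stop_reason, weights = w, net = net),
            class = "nf_train_report")
}

#' @export
print.nf_train_report <- function(x, ...) {
  h <- x$history
  cat(sprintf("<nf_train_report> %d epochs (%s), best epoch %d\n", nrow(h),
              x$stop_reason, x$best_epoch))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train loss %.4f; best val loss %.4f\n",
                last$train_loss,
                if (x$best_epoch > 0) min(h$val_loss, na.rm = TRUE) else NA))
  }
  invisible(x)
}
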