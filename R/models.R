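# classifier architectures
#
# EEG: compact CNN of four blocks (3x3 convolution with padding 1 over the
# channel x time grid -> batch normalization -> ReLU -> temporal max-pool
# by 2), filter counts 32/64/128/256, adaptive average pooling to a fixed
# 256-vector, MLP 256 -> 128 (ReLU, dropout 0.5) -> 2 logits. The
# embedding size is independent of the window length; any window with at
# least 16 samples is accepted, which covers the whole ablation grid
# (1-8 s at 128 Hz).
#
# EDA: 2-layer bidirectional LSTM, 64 hidden units per direction; the final
# representation concatenates the last forward and first backward hidden
# states (R^128), followed by an MLP 128 -> 64 (ReLU, dropout) -> 2 logits.
#
# Both networks are implemented in compiled code; see src/networks.cpp.

new_nf_net <- function(ptr, kind, config) {
  structure(list(ptr = ptr, kind = kind, config = config), class = "nf_net")
}

#' EEG convolutional network
#'
#' Creates the 4-block CNN for raw EEG windows (see the package vignette
#' for the architecture). Weights are initialized reproducibly from `seed`.
#'
#' @param n_channels EEG channel count (default 14).
#' @param dropout dropout probability in the MLP head.
#' @param seed integer seed for weight initialization and dropout.
#' @param precision `"single"` (fast, default) or `"double"` (used by
#'   gradient-accuracy checks).
#' @return an `nf_net` object.
#' @export
eeg_cnn <- function(n_channels = 14, dropout = 0.5, seed = 1,
                    precision = c("single", "double")) {
  precision <- match.arg(precision)
  cfg <- list(type = "cnn", n_channels = n_channels, dropout = dropout,
              seed = seed, precision = precision,
              block_filters = c(32, 64, 128, 256), embedding_dim = 256,
              mlp_hidden = 128, n_classes = 2)
  new_nf_net(nf_cnn_create(as.integer(n_channels), dropout, as.integer(seed),
                           precision), "cnn", cfg)
}

#' EDA bidirectional LSTM
#'
#' Creates the 2-layer BiLSTM for univariate EDA windows.
#'
#' @param input_dim input channels per time step (1 for conductance).
#' @inheritParams eeg_cnn
#' @return an `nf_net` object.
#' @export
eda_bilstm <- function(input_dim = 1, dropout = 0.5, seed = 1,
                       precision = c("single", "double")) {
  precision <- match.arg(precision)
  cfg <- list(type = "lstm", input_dim = input_dim, dropout = dropout,
              seed = seed, precision = precision, layers = 2,
              hidden_per_direction = 64, mlp_hidden = 64, n_classes = 2)
  new_nf_net(nf_lstm_create(as.integer(input_dim), dropout, as.integer(seed),
                            precision), "lstm", cfg)
}

#' @export
print.nf_net <- function(x, ...) {
  cat(sprintf("<nf_net> %s (%s precision), %s learnable parameters\n",
              if (x$kind == "cnn") "EEG CNN (4 blocks, 32/64/128/256)"
              else "EDA BiLSTM (2 layers, 64/direction)",
              x$config$precision,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count learnable parameters
#'
#' Exact number of learnable scalars of a network (batch-norm running
#' statistics are state, not parameters, and are excluded). The count is
#' independent of the input window length because adaptive pooling (CNN)
#' and recurrence (LSTM) decouple the architecture from T.
#'
#' @param net an `nf_net`.
#' @return integer count.
#' @export
count_parameters <- function(net) {
  as.integer(nf_net_nparams(net$ptr))
}

# convert a window set (or raw array/matrix) to the input the backend wants
net_input <- function(net, x) {
  if (inherits(x, "nf_windows")) x <- x$x
  if (net$kind == "cnn") {
    if (length(dim(x)) != 3) stop("EEG input must be an (n, channels, T) array")
    return(x)
  }
  if (length(dim(x)) == 3) {
    if (dim(x)[2] != 1) stop("the EDA network takes univariate sequences")
    x <- array(x, c(dim(x)[1], dim(x)[3]))
  }
  if (is.null(dim(x))) x <- matrix(x, 1)
  x
}

#' Network forward pass (logits)
#'
#' Computes the two-class logits for a batch of windows. In evaluation mode
#' (default) the map is deterministic (running batch-norm statistics, no
#' dropout); with `train_mode = TRUE` batch statistics and dropout are
#' active, so repeated calls differ.
#'
#' @param net an `nf_net`.
#' @param x an `nf_windows`, an (n, channels, T) array (CNN) or an (n, T)
#'   matrix (LSTM).
#' @param train_mode use training-mode stochastic forward pass.
#' @param batch_size evaluation batch size.
#' @return numeric matrix (n x 2) of logits.
#' @export
net_logits <- function(net, x, train_mode = FALSE, batch_size = 256) {
  x <- net_input(net, x)
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  out <- matrix(0, n, 2)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    xb <- if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx, , , drop = FALSE]
    out[idx, ] <- nf_net_logits(net$ptr, xb, train_mode)
    at <- at + batch_size
  }
  out
}

#' @export
predict.nf_net <- function(object, newdata, type = c("logits", "prob"), ...) {
  type <- match.arg(type)
  z <- net_logits(object, newdata)
  if (type == "prob") softmax_rows(z) else z
}

net_get_params <- function(net) {
  list(params = nf_net_get_params(net$ptr), state = nf_net_get_state(net$ptr))
}

net_set_params <- function(net, snapshot) {
  nf_net_set_params(net$ptr, snapshot$params)
  if (length(snapshot$state)) nf_net_set_state(net$ptr, snapshot$state)
  invisible(net)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are JSON files with a header (architecture config, seed,
#' optional epoch) followed by all parameters and batch-norm state, so they
#' are portable across platforms.
#'
#' @param net an `nf_net`.
#' @param path file path.
#' @param epoch optional epoch tag stored in the header.
#' @return `save_checkpoint()` the path invisibly; `load_checkpoint()` a
#'   reconstructed `nf_net`.
#' @export
save_checkpoint <- function(net, path, epoch = NULL) {
  snap <- net_get_params(net)
  obj <- list(header = c(net$config, list(epoch = epoch)),
              params = snap$params, state = snap$state)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$header
  net <- if (identical(h$type, "cnn")) {
    eeg_cnn(h$n_channels, h$dropout, h$seed, h$precision)
  } else {
    eda_bilstm(h$input_dim, h$dropout, h$seed, h$precision)
  }
  params <- lapply(obj$params, function(p) {
    if (is.null(dim(p))) matrix(p, ncol = 1) else p
  })
  nf_net_set_params(net$ptr, params)
  if (length(obj$state)) nf_net_set_state(net$ptr, as.list(obj$state))
  net$config <- h[setdiff(names(h), "epoch")]
  net
}
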