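# network architectures: shape contracts across the ablation grid,
# parameter counts, train/eval mode semantics, gradient correctness

test_that("CNN accepts every EEG window length of the ablation grid", {
  net <- eeg_cnn(seed = 1)
  for (w in c(1, 2, 4, 6, 8)) {
    z <- net_logits(net, array(rnorm(2 * 14 * (128 * w)), c(2, 14, 128 * w)))
    expect_equal(dim(z), c(2, 2), info = paste(w, "s"))
    expect_true(all(is.finite(z)))
  }
  expect_error(net_logits(net, array(0, c(1, 14, 8))), "16")
  expect_error(net_logits(net, array(0, c(1, 10, 64))), "channel count")
})

test_that("BiLSTM accepts every EDA window length of the ablation grid", {
  net <- eda_bilstm(seed = 1)
  for (w in c(5, 10, 15, 20, 30)) {
    z <- net_logits(net, matrix(rnorm(3 * 4 * w), 3, 4 * w))
    expect_equal(dim(z), c(3, 2), info = paste(w, "s"))
    expect_true(all(is.finite(z)))
  }
  expect_error(net_logits(net, matrix(0, 1, 1)), "too short")
})

test_that("zeroing the output layer yields identically zero logits", {
  for (net in list(eeg_cnn(seed = 2), eda_bilstm(seed = 2))) {
    p <- noisefuse:::nf_net_get_params(net$ptr)
    p$fc2_w[] <- 0
    p$fc2_b[] <- 0
    noisefuse:::nf_net_set_params(net$ptr, p)
    x <- if (net$kind == "cnn") array(rnorm(2 * 14 * 64), c(2, 14, 64))
         else matrix(rnorm(2 * 20), 2, 20)
    expect_equal(net_logits(net, x), matrix(0, 2, 2))
  }
})

test_that("parameter counts equal the closed-form sums", {
  # CNN: conv blocks + batch-norm affine + MLP head
  conv <- 32 * 1 * 9 + 32 + 64 * 32 * 9 + 64 + 128 * 64 * 9 + 128 +
    256 * 128 * 9 + 256
  bn <- 2 * (32 + 64 + 128 + 256)
  head <- 128 * 256 + 128 + 2 * 128 + 2
  expect_equal(count_parameters(eeg_cnn(seed = 1)), conv + bn + head)
  # LSTM: per (layer, direction) W_ih, W_hh and one bias; MLP head
  l1 <- 2 * (4 * 64 * 1 + 4 * 64 * 64 + 4 * 64)
  l2 <- 2 * (4 * 64 * 128 + 4 * 64 * 64 + 4 * 64)
  mlp <- (128 * 64 + 64) + (64 * 2 + 2) # the documented 8386-scalar head
  expect_equal(mlp, 8386)
  expect_equal(count_parameters(eda_bilstm(seed = 1)), l1 + l2 + mlp)
  # counts do not depend on the window length (adaptive pooling/recurrence)
  net <- eeg_cnn(seed = 3)
  invisible(net_logits(net, array(0, c(1, 14, 128))))
  n1 <- count_parameters(net)
  invisible(net_logits(net, array(0, c(1, 14, 1024))))
  expect_equal(count_parameters(net), n1)
})

test_that("eval mode is deterministic, train mode is stochastic", {
  net <- eeg_cnn(seed = 5)
  x <- array(rnorm(4 * 14 * 64), c(4, 14, 64))
  expect_identical(net_logits(net, x), net_logits(net, x))
  t1 <- net_logits(net, x, train_mode = TRUE)
  t2 <- net_logits(net, x, train_mode = TRUE)
  expect_gt(max(abs(t1 - t2)), 0) # dropout resamples
  nl <- eda_bilstm(seed = 5)
  xm <- matrix(rnorm(4 * 20), 4, 20)
  expect_identical(net_logits(nl, xm), net_logits(nl, xm))
  expect_gt(max(abs(net_logits(nl, xm, TRUE) - net_logits(nl, xm, TRUE))), 0)
})

test_that("analytic gradients match finite differences (double precision)", {
  set.seed(6)
  check_grad <- function(net, x, y, n_check = 40, h = 1e-6, l1 = 1e-3) {
    w <- c(1, 1.3)
    lg <- noisefuse:::nf_net_loss_grad(net$ptr, x, y, w, l1, TRUE)
    th <- noisefuse:::nf_net_get_theta(net$ptr)
    idx <- sample(length(th), n_check)
    num <- vapply(idx, function(i) {
      tp <- th; tp[i] <- th[i] + h
      noisefuse:::nf_net_set_theta(net$ptr, tp)
      up <- noisefuse:::nf_net_loss_grad(net$ptr, x, y, w, l1, FALSE)$loss
      tp[i] <- th[i] - h
      noisefuse:::nf_net_set_theta(net$ptr, tp)
      dn <- noisefuse:::nf_net_loss_grad(net$ptr, x, y, w, l1, FALSE)$loss
      noisefuse:::nf_net_set_theta(net$ptr, th)
      (up - dn) / (2 * h)
    }, 0)
    max(abs(num - lg$grad[idx]))
  }
  cnn <- eeg_cnn(seed = 6, precision = "double")
  err_c <- check_grad(cnn, array(rnorm(3 * 14 * 16), c(3, 14, 16)),
                      c(0L, 1L, 1L))
  expect_lt(err_c, 1e-5)
  lstm <- eda_bilstm(seed = 6, precision = "double")
  err_l <- check_grad(lstm, matrix(rnorm(4 * 9), 4, 9), c(0L, 1L, 0L, 1L))
  expect_lt(err_l, 1e-5)
})

test_that("one optimization step reduces the batch loss", {
  set.seed(7)
  for (kind in c("cnn", "lstm")) {
    net <- if (kind == "cnn") eeg_cnn(seed = 7) else eda_bilstm(seed = 7)
    x <- if (kind == "cnn") array(rnorm(8 * 14 * 16), c(8, 14, 16))
         else matrix(rnorm(8 * 12), 8, 12)
    y <- rep(c(0L, 1L), 4)
    before <- noisefuse:::nf_net_loss_grad(net$ptr, x, y, c(1, 1), 0, FALSE)$loss
    noisefuse:::nf_net_train_batch(net$ptr, x, y, c(1, 1), 1e-3, 0, 0)
    after <- noisefuse:::nf_net_loss_grad(net$ptr, x, y, c(1, 1), 0, FALSE)$loss
    expect_lt(after, before)
  }
})

test_that("checkpoints round-trip parameters and batch-norm state", {
  net <- eeg_cnn(seed = 8)
  x <- array(rnorm(4 * 14 * 32), c(4, 14, 32))
  invisible(noisefuse:::nf_net_train_batch(net$ptr, x, rep(0:1, 2), c(1, 1),
                                           1e-3, 0, 0))
  path <- tempfile(fileext = ".json")
  save_checkpoint(net, path, epoch = 1)
  back <- load_checkpoint(path)
  expect_equal(net_logits(back, x), net_logits(net, x), tolerance = 1e-6)
  unlink(path)
})
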