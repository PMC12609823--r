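# the central model-fitting function
#
# annoyance_fit() trains the full multimodal classifier on one training
# pool: it carves out the validation windows (split 1:1 into calibration
# and fusion/threshold subsets), fits standardizers on the remaining
# training windows only, augments them, trains the EEG CNN and EDA BiLSTM,
# fits one temperature per modality on the calibration subset, F1-optimal
# thresholds and the fusion model on the fusion subset, and evaluates the
# validation gate (fusion deployed only if strictly better than EEG on
# both accuracy and F1).

#' Stratified validation split
#'
#' Samples `val_fraction` of the windows (stratified by label), then halves
#' the sampled set 1:1 (per label, odd counts rounded toward calibration)
#' into the calibration and fusion/threshold subsets. Falls back to an
#' unstratified split, with a warning, when a class has too few windows.
#'
#' @param labels integer 0/1 window labels.
#' @param val_fraction fraction in (0, 0.5].
#' @param seed RNG seed.
#' @return list of index vectors `train`, `cal`, `fus` (disjoint, covering
#'   all windows).
#' @export
split_validation <- function(labels, val_fraction = 0.15, seed = 1) {
  if (val_fraction <= 0 || val_fraction > 0.5)
    stop("'val_fraction' must lie in (0, 0.5]")
  n <- length(labels)
  strata <- if (min(table(factor(labels, levels = 0:1))) < 4) {
    warning("too few windows in a class to stratify: unstratified split")
    list(seq_len(n))
  } else {
    list(which(labels == 0), which(labels == 1))
  }
  cal <- fus <- integer(0)
  odd_to_cal <- TRUE # alternate which half receives an odd stratum's extra
  with_seed(seed, {
    for (idx in strata) {
      m <- length(idx)
      nv <- round(val_fraction * m)
      pick <- sample(idx, nv)
      ncal <- floor(nv / 2)
      if (nv %% 2 == 1) {
        if (odd_to_cal) ncal <- ncal + 1
        odd_to_cal <- !odd_to_cal
      }
      cal <- c(cal, pick[seq_len(ncal)])
      if (nv > ncal) fus <- c(fus, pick[(ncal + 1):nv])
    }
  })
  list(train = setdiff(seq_len(n), c(cal, fus)), cal = sort(cal),
       fus = sort(fus))
}

# stratified cap on training windows for desk-scale runs
cap_windows <- function(ws, max_n, seed) {
  n <- n_windows(ws)
  if (is.null(max_n) || n <= max_n) return(ws)
  idx <- integer(0)
  with_seed(seed, {
    for (cl in 0:1) {
      icl <- which(ws$y == cl)
      keep <- max(1L, round(max_n * length(icl) / n))
      idx <- c(idx, sample(icl, min(keep, length(icl))))
    }
  })
  windows_subset(ws, sort(idx))
}

#' Fit the multimodal annoyance classifier
#'
#' Trains the complete model on a pool of (unstandardized) EEG and EDA
#' windows: leakage-safe standardization, augmentation, CNN and BiLSTM
#' training with early stopping, temperature calibration, F1-optimal
#' thresholding, decision-level fusion, and the validation gate. The
#' returned object predicts on new windows via [predict.annoyance_fit()].
#'
#' @param eeg,eda `nf_windows` sets from the same sessions (training pool).
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return object of class `annoyance_fit`.
#' @export
annoyance_fit <- function(eeg, eda, config = pipeline_config(),
                          verbose = FALSE) {
  sp_e <- split_validation(eeg$y, config$val_fraction, config$seed)
  sp_d <- split_validation(eda$y, config$val_fraction, config$seed + 1L)

  tr_e <- windows_subset(eeg, sp_e$train, split = "train")
  stats_e <- fit_standardizer(tr_e)
  eeg_std <- apply_standardizer(eeg, stats_e)
  tr_e <- windows_subset(eeg_std, sp_e$train, split = "train")
  tr_e <- cap_windows(tr_e, config$max_train_windows, config$seed + 11L)
  tr_e <- augment_windows(tr_e, config$aug_k, config$aug_sd_max,
                          seed = config$seed + 21L)
  val_e <- windows_subset(eeg_std, c(sp_e$cal, sp_e$fus), split = "val")

  tr_d <- windows_subset(eda, sp_d$train, split = "train")
  stats_d <- fit_standardizer(tr_d)
  eda_std <- apply_standardizer(eda, stats_d)
  tr_d <- windows_subset(eda_std, sp_d$train, split = "train")
  tr_d <- cap_windows(tr_d, config$max_train_windows, config$seed + 12L)
  tr_d <- augment_windows(tr_d, config$aug_k, config$aug_sd_max,
                          seed = config$seed + 22L)
  val_d <- windows_subset(eda_std, c(sp_d$cal, sp_d$fus), split = "val")

  tc <- function(off, epochs) train_config(
    batch_size = config$batch_size, lr = config$lr,
    weight_decay = config$weight_decay, l1_lambda = config$l1_lambda,
    max_epochs = epochs, patience = config$patience,
    lr_factor = config$lr_factor, lr_patience = config$lr_patience,
    aug_k = 0, seed = config$seed + off)
  eda_epochs <- if (!is.null(config$eda_max_epochs)) config$eda_max_epochs
                else config$max_epochs

  if (verbose) message("training EEG CNN on ", n_windows(tr_e), " windows")
  net_e <- eeg_cnn(dim(eeg$x)[2], seed = config$seed)
  rep_e <- train_network(net_e, tr_e, val_e, tc(100L, config$max_epochs),
                         verbose = verbose)
  if (verbose) message("training EDA BiLSTM on ", n_windows(tr_d), " windows")
  net_d <- eda_bilstm(seed = config$seed + 1L)
  rep_d <- train_network(net_d, tr_d, val_d, tc(200L, eda_epochs),
                         verbose = verbose)

  # temperature scaling on the calibration subset
  temp_e <- fit_temperature(net_logits(net_e, windows_subset(eeg_std, sp_e$cal)),
                            eeg$y[sp_e$cal])
  temp_d <- fit_temperature(net_logits(net_d, windows_subset(eda_std, sp_d$cal)),
                            eda$y[sp_d$cal])

  # F1-optimal thresholds on the fusion/threshold subset
  p_e_fus <- calibrate_probs(net_logits(net_e, windows_subset(eeg_std, sp_e$fus)),
                             temp_e)[, 2]
  p_d_fus <- calibrate_probs(net_logits(net_d, windows_subset(eda_std, sp_d$fus)),
                             temp_d)[, 2]
  rule_e <- fit_threshold(p_e_fus, eeg$y[sp_e$fus], config$threshold_objective)
  rule_d <- fit_threshold(p_d_fus, eda$y[sp_d$fus], config$threshold_objective)

  fusion <- NULL
  rule_f <- NULL
  gate <- NA_character_
  if (!config$fusion %in% c("eeg_only", "eda_only")) {
    # pair the EEG fusion-subset windows with same-session EDA windows
    fus_eeg <- windows_subset(eeg_std, sp_e$fus)
    pairs <- pair_windows(fus_eeg, eda_std)
    p_pair_d <- calibrate_probs(
      net_logits(net_d, windows_subset(eda_std, pairs$eda_idx)), temp_d)[, 2]
    p_pair_e <- p_e_fus[pairs$eeg_idx]
    y_pair <- fus_eeg$y[pairs$eeg_idx]
    fusion <- fit_fusion(config$fusion, p_pair_e, p_pair_d, y_pair)
    p_fused <- fuse_probs(fusion, p_pair_e, p_pair_d)
    rule_f <- fit_threshold(p_fused, y_pair, config$threshold_objective)
    m_fus <- compute_metrics(as.integer(p_fused >= rule_f$tau), p_fused, y_pair)
    m_eeg <- compute_metrics(as.integer(p_pair_e >= rule_e$tau), p_pair_e,
                             y_pair)
    gate <- gate_decision(m_fus, m_eeg)
  }

  structure(list(
    nets = list(eeg = net_e, eda = net_d),
    stats = list(eeg = stats_e, eda = stats_d),
    temperatures = list(eeg = temp_e, eda = temp_d),
    rules = list(eeg = rule_e, eda = rule_d, fused = rule_f),
    fusion = fusion, gate = gate,
    train_reports = list(eeg = rep_e, eda = rep_d),
    config = config,
    split_sizes = list(
      eeg = vapply(sp_e, length, 0L), eda = vapply(sp_d, length, 0L))
  ), class = "annoyance_fit")
}

#' @export
print.annoyance_fit <- function(x, ...) {
  cat("Multimodal annoyance classifier (EEG CNN + EDA BiLSTM)\n")
  cat(sprintf("  fusion: %s; gate outcome: %s\n", x$config$fusion, x$gate))
  cat(sprintf("  temperatures: EEG %.3f, EDA %.3f\n",
              x$temperatures$eeg$t_hat, x$temperatures$eda$t_hat))
  cat(sprintf("  thresholds: EEG %.3f, EDA %.3f%s\n", x$rules$eeg$tau,
              x$rules$eda$tau,
              if (!is.null(x$rules$fused))
                sprintf(", fused %.3f", x$rules$fused$tau) else ""))
  invisible(x)
}

#' @export
summary.annoyance_fit <- function(object, ...) {
  cat("Multimodal annoyance classifier\n\n")
  print(object$config)
  cat(sprintf("\nEEG CNN: %s parameters, trained %d epochs (best %d)\n",
              format(count_parameters(object$nets$eeg), big.mark = ","),
              nrow(object$train_reports$eeg$history),
              object$train_reports$eeg$best_epoch))
  cat(sprintf("EDA BiLSTM: %s parameters, trained %d epochs (best %d)\n",
              format(count_parameters(object$nets$eda), big.mark = ","),
              nrow(object$train_reports$eda$history),
              object$train_reports$eda$best_epoch))
  cat(sprintf("\nsplit sizes (EEG): train %d / cal %d / fus %d\n",
              object$split_sizes$eeg["train"], object$split_sizes$eeg["cal"],
              object$split_sizes$eeg["fus"]))
  print(object)
  invisible(object)
}

#' @export
coef.annoyance_fit <- function(object, ...) {
  out <- c(t_eeg = object$temperatures$eeg$t_hat,
           t_eda = object$temperatures$eda$t_hat,
           tau_eeg = object$rules$eeg$tau, tau_eda = object$rules$eda$tau)
  if (!is.null(object$rules$fused))
    out <- c(out, tau_fused = object$rules$fused$tau)
  if (!is.null(object$fusion) && length(object$fusion$model)) {
    fm <- unlist(object$fusion$model)
    names(fm) <- paste0("fusion.", names(fm))
    out <- c(out, fm)
  }
  out
}

#' @export
plot.annoyance_fit <- function(x, ...) {
  he <- x$train_reports$eeg$history
  hd <- x$train_reports$eda$history
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  for (h in list(list(d = he, t = "EEG CNN"), list(d = hd, t = "EDA BiLSTM"))) {
    graphics::plot(h$d$epoch, h$d$train_loss, type = "l", xlab = "epoch",
                   ylab = "loss", main = h$t, ...)
    if (any(!is.na(h$d$val_loss)))
      graphics::lines(h$d$epoch, h$d$val_loss, lty = 2)
  }
  invisible(x)
}

#' Predict from a fitted annoyance classifier
#'
#' Standardizes the supplied windows with the training statistics,
#' computes calibrated per-modality probabilities and thresholded classes,
#' and — when the model fused and `eda` windows are supplied — the fused
#' probabilities and the deployed (gated) prediction.
#'
#' @param object an `annoyance_fit`.
#' @param eeg `nf_windows` of EEG windows (unstandardized).
#' @param eda optional matching `nf_windows` of EDA windows.
#' @param ... unused.
#' @return data.frame with per-EEG-window columns `p_eeg`, `class_eeg`,
#'   and (with `eda`) `p_eda`, `p_fused`, `p_applied`, `class_applied`,
#'   plus `label` when the windows carry labels.
#' @export
predict.annoyance_fit <- function(object, eeg, eda = NULL, ...) {
  eeg_std <- apply_standardizer(eeg, object$stats$eeg)
  p_e <- calibrate_probs(net_logits(object$nets$eeg, eeg_std),
                         object$temperatures$eeg)[, 2]
  out <- data.frame(p_eeg = p_e,
                    class_eeg = as.integer(p_e >= object$rules$eeg$tau))
  if (!is.null(eda)) {
    eda_std <- apply_standardizer(eda, object$stats$eda)
    pairs <- pair_windows(eeg_std, eda_std)
    p_d_all <- calibrate_probs(net_logits(object$nets$eda, eda_std),
                               object$temperatures$eda)[, 2]
    p_d <- rep(NA_real_, nrow(out))
    p_d[pairs$eeg_idx] <- p_d_all[pairs$eda_idx]
    out$p_eda <- p_d
    if (!is.null(object$fusion)) {
      pf <- rep(NA_real_, nrow(out))
      ok <- !is.na(p_d)
      pf[ok] <- fuse_probs(object$fusion, p_e[ok], p_d[ok])
      out$p_fused <- pf
      use_fusion <- identical(object$gate, "use_fusion")
      out$p_applied <- if (use_fusion) pf else p_e
      tau <- if (use_fusion) object$rules$fused$tau else object$rules$eeg$tau
      out$class_applied <- as.integer(out$p_applied >= tau)
    }
  }
  if (length(eeg$y)) out$label <- eeg$y
  out
}
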