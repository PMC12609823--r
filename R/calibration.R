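# calibration and decision-level fusion: temperature scaling, F1-optimal
# thresholding, stacked / weighted / gated late fusion, and the
# validation-gated EEG fallback

#' Fit a temperature for logit calibration
#'
#' Finds `t > 0` minimizing the mean cross-entropy of `softmax(z / t)` on a
#' held-out calibration subset, by bounded 1-D minimization over
#' `log t` in [-4, 4]. Temperature scaling never changes the predicted
#' class, only the confidence.
#'
#' @param logits n x 2 logit matrix (calibration subset).
#' @param labels integer 0/1 labels.
#' @return list of class `nf_temperature` with element `t_hat`.
#' @export
fit_temperature <- function(logits, labels) {
  if (length(unique(labels)) < 2) {
    warning("single-class calibration labels: temperature fixed at 1")
    return(structure(list(t_hat = 1), class = "nf_temperature"))
  }
  nll <- function(logt) {
    p <- softmax_rows(logits / exp(logt))
    py <- ifelse(labels == 1, p[, 2], p[, 1])
    -mean(log(pmax(py, 1e-30)))
  }
  opt <- optimize(nll, interval = c(-4, 4))
  structure(list(t_hat = exp(opt$minimum)), class = "nf_temperature")
}

#' Calibrate logits with a temperature
#'
#' `P = softmax(z / t_hat)`; rows sum to one and the class ranking is
#' preserved for any positive temperature.
#'
#' @param logits n x 2 logit matrix.
#' @param temperature an `nf_temperature` (or positive scalar).
#' @return n x 2 matrix of calibrated probabilities.
#' @export
calibrate_probs <- function(logits, temperature) {
  t_hat <- if (inherits(temperature, "nf_temperature")) temperature$t_hat
           else temperature
  if (!is.numeric(t_hat) || t_hat <= 0) stop("temperature must be positive")
  softmax_rows(logits / t_hat)
}

# F1 of the high class and macro-F1 for a given cut; used by the
# threshold scan and the weighted-fusion grid
f1_at <- function(scores, labels, tau, objective = "macro") {
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  f1c <- function(tp, fp, fn) {
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }
  if (objective == "high") f1c(tp, fp, fn)
  else (f1c(tp, fp, fn) + f1c(tn, fn, fp)) / 2
}

#' F1-optimal decision threshold
#'
#' Scans candidate thresholds at the midpoints of sorted unique scores
#' plus {0, 1} and returns the threshold maximizing F1 on the supplied
#' (fusion/threshold) subset. Ties are broken toward the smaller
#' threshold. Predictions use the rule `score >= tau -> high`. The default
#' objective is macro-F1 so that both classes contribute equally (matching
#' how all other metrics are averaged); `objective = "high"` maximizes the
#' high-class F1 instead.
#'
#' @param scores calibrated P(high) in [0, 1].
#' @param labels integer 0/1 labels.
#' @param objective `"macro"` or `"high"`.
#' @return list of class `nf_decision_rule` with `tau`, `f1`, `objective`.
#' @export
fit_threshold <- function(scores, labels, objective = c("macro", "high")) {
  objective <- match.arg(objective)
  if (length(unique(labels)) < 2) {
    warning("single-class threshold subset: tau fixed at 0.5")
    return(structure(list(tau = 0.5, f1 = NA_real_, objective = objective),
                     class = "nf_decision_rule"))
  }
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  f1 <- vapply(cand, function(tau) f1_at(scores, labels, tau, objective), 0)
  best <- which(f1 >= max(f1) - 1e-12)[1] # smallest tau among ties
  structure(list(tau = cand[best], f1 = f1[best], objective = objective),
            class = "nf_decision_rule")
}

#' Fit a decision-level fusion model
#'
#' Combines calibrated per-modality probabilities on the fusion/threshold
#' subset:
#' * `stacked` — logistic-regression meta-classifier on
#'   (P_eeg(high), P_eda(high));
#' * `weighted` — convex combination `w * P_eeg + (1 - w) * P_eda`, `w`
#'   chosen on the grid 0, 0.05, ..., 1 maximizing validation F1 (at each
#'   w's own F1-optimal threshold);
#' * `gated` — per-sample mixing weight
#'   `g = sigmoid(a . [pe, pd, |pe - 0.5|, |pd - 0.5|] + b)` with (a, b)
#'   fitted by gradient descent (BFGS) on the cross-entropy of
#'   `g * P_eeg + (1 - g) * P_eda`;
#' * `eeg_only` / `eda_only` — pass-through of one modality.
#'
#' @param strategy fusion strategy.
#' @param p_eeg,p_eda calibrated P(high) vectors, paired per
#'   [pair_windows()].
#' @param labels integer 0/1 labels of the paired windows.
#' @return list of class `nf_fusion`.
#' @export
fit_fusion <- function(strategy = c("stacked", "weighted", "gated",
                                    "eeg_only", "eda_only"),
                       p_eeg, p_eda, labels) {
  strategy <- match.arg(strategy)
  if (length(p_eeg) != length(p_eda) || length(p_eeg) != length(labels))
    stop("fusion inputs must be paired vectors of equal length")
  model <- switch(strategy,
    stacked = {
      df <- data.frame(y = labels, pe = p_eeg, pd = p_eda)
      fit <- suppressWarnings(glm(y ~ pe + pd, data = df, family = binomial()))
      list(coef = coef(fit))
    },
    weighted = {
      grid <- seq(0, 1, by = 0.05)
      f1 <- vapply(grid, function(w) {
        p <- w * p_eeg + (1 - w) * p_eda
        fit_threshold(p, labels)$f1
      }, 0)
      list(w = grid[which.max(f1)])
    },
    gated = {
      feats <- cbind(p_eeg, p_eda, abs(p_eeg - 0.5), abs(p_eda - 0.5))
      obj <- function(par) {
        g <- plogis(drop(feats %*% par[1:4]) + par[5])
        p <- g * p_eeg + (1 - g) * p_eda
        -mean(labels * log(pmax(p, 1e-12)) +
                (1 - labels) * log(pmax(1 - p, 1e-12)))
      }
      fit <- optim(rep(0, 5), obj, method = "BFGS",
                   control = list(maxit = 200))
      list(par = fit$par)
    },
    eeg_only = list(),
    eda_only = list()
  )
  structure(list(strategy = strategy, model = model), class = "nf_fusion")
}

#' Apply a fusion model
#'
#' @param fusion an `nf_fusion` from [fit_fusion()].
#' @param p_eeg,p_eda calibrated P(high) vectors.
#' @return fused P(high) vector.
#' @export
fuse_probs <- function(fusion, p_eeg, p_eda) {
  switch(fusion$strategy,
    stacked = {
      b <- fusion$model$coef
      plogis(b[1] + b[2] * p_eeg + b[3] * p_eda)
    },
    weighted = fusion$model$w * p_eeg + (1 - fusion$model$w) * p_eda,
    gated = {
      par <- fusion$model$par
      feats <- cbind(p_eeg, p_eda, abs(p_eeg - 0.5), abs(p_eda - 0.5))
      g <- plogis(drop(feats %*% par[1:4]) + par[5])
      g * p_eeg + (1 - g) * p_eda
    },
    eeg_only = p_eeg,
    eda_only = p_eda
  )
}

#' Validation gate: fusion vs the EEG branch
#'
#' Fusion is deployed on the test fold only when it is strictly superior to
#' the EEG branch on the fusion-validation subset in BOTH accuracy and F1;
#' equality on either metric falls back to EEG.
#'
#' @param metrics_fusion,metrics_eeg metric lists (from [compute_metrics()]
#'   or any list with `accuracy` and `f1`) computed on the same
#'   fusion-validation subset.
#' @return `"use_fusion"` or `"use_eeg"`.
#' @export
gate_decision <- function(metrics_fusion, metrics_eeg) {
  if (metrics_fusion$accuracy > metrics_eeg$accuracy &&
      metrics_fusion$f1 > metrics_eeg$f1) "use_fusion" else "use_eeg"
}
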