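# evaluation metrics: confusion-matrix accuracy, macro-averaged
# precision/recall/F1, rank-based AUROC with midrank tie handling,
# step-integrated AUPRC, and across-fold aggregation (mean, CoV, 95% CI)

#' Compute classification metrics for one fold
#'
#' Accuracy is read off the confusion matrix; precision, recall and F1 are
#' macro-averaged over the two classes (undefined per-class ratios count
#' as 0); AUROC is the rank statistic of P(high) with midrank handling of
#' ties; AUPRC is the step integration of precision over recall (average
#' precision). With single-class labels AUROC/AUPRC are recorded as `NA`
#' with a warning.
#'
#' @param predictions integer 0/1 predicted labels.
#' @param scores calibrated P(high) used for ranking metrics.
#' @param labels integer 0/1 true labels.
#' @return list of class `nf_metrics`: `accuracy`, `precision`, `recall`,
#'   `f1`, `auroc`, `auprc`, `confusion` (2 x 2 matrix), `n`.
#' @export
compute_metrics <- function(predictions, scores, labels) {
  stopifnot(length(predictions) == length(labels),
            length(scores) == length(labels))
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  conf <- matrix(c(tn, fp, fn, tp), 2, 2,
                 dimnames = list(pred = c("normal", "high"),
                                 truth = c("normal", "high")))
  acc <- (tp + tn) / length(labels)
  prf <- function(tp, fp, fn) {
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    c(pr, rc, f1)
  }
  hi <- prf(tp, fp, fn)
  lo <- prf(tn, fn, fp)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class labels: AUROC/AUPRC undefined")
    auroc <- auprc <- NA_real_
  } else {
    r <- rank(scores) # midranks for ties
    auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
    auprc <- average_precision(scores, labels)
  }
  structure(list(accuracy = acc,
                 precision = (hi[1] + lo[1]) / 2,
                 recall = (hi[2] + lo[2]) / 2,
                 f1 = (hi[3] + lo[3]) / 2,
                 auroc = auroc, auprc = auprc,
                 confusion = conf, n = length(labels)),
            class = "nf_metrics")
}

# average precision: sum over distinct descending score levels of
# precision * recall increment (trapezoid-free step integration)
average_precision <- function(scores, labels) {
  n1 <- sum(labels == 1)
  lev <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- 0
  prev_rec <- 0
  ap <- 0
  for (s in lev) {
    at <- scores == s
    tp <- tp + sum(labels[at] == 1)
    fp <- fp + sum(labels[at] == 0)
    rec <- tp / n1
    prec <- tp / (tp + fp)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

#' @export
print.nf_metrics <- function(x, ...) {
  cat(sprintf(
    "<nf_metrics> n=%d  acc %.3f  prec %.3f  rec %.3f  F1 %.3f  AUROC %s  AUPRC %s\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1,
    ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
    ifelse(is.na(x$auprc), "NA", sprintf("%.3f", x$auprc))))
  invisible(x)
}

#' Aggregate fold metrics
#'
#' For each metric: mean over folds, fold-to-fold coefficient of variation
#' CoV% = 100 * sd / mean (sample SD, `NA` when the mean is 0), and the
#' Student-t 95% confidence interval `mean +- t(0.975, k-1) * sd / sqrt(k)`
#' (multiplier 2.776 for 5 folds).
#'
#' @param fold_metrics list of `nf_metrics` (or metric lists), length >= 2.
#' @return data.frame with columns `metric`, `mean`, `cov_pct`, `ci_lo`,
#'   `ci_hi`.
#' @export
aggregate_folds <- function(fold_metrics) {
  if (length(fold_metrics) < 2) stop("need at least 2 folds to aggregate")
  metrics <- c("accuracy", "precision", "recall", "f1", "auroc", "auprc")
  k <- length(fold_metrics)
  rows <- lapply(metrics, function(m) {
    v <- vapply(fold_metrics, function(f) as.numeric(f[[m]]), 0)
    v <- v[!is.na(v)]
    if (length(v) < 2)
      return(data.frame(metric = m, mean = if (length(v)) mean(v) else NA,
                        cov_pct = NA, ci_lo = NA, ci_hi = NA))
    mu <- mean(v)
    s <- sd(v)
    half <- qt(0.975, length(v) - 1) * s / sqrt(length(v))
    data.frame(metric = m, mean = mu,
               cov_pct = if (mu != 0) 100 * s / mu else NA_real_,
               ci_lo = mu - half, ci_hi = mu + half)
  })
  do.call(rbind, rows)
}
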