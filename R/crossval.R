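# subject-grouped cross-validated evaluation
#
# All windows of a participant are assigned to exactly one fold
# (GroupKFold), so test subjects are never seen during training,
# calibration, thresholding or model choice.

#' Plan subject-grouped folds
#'
#' Shuffles the subjects with `seed` and deals them round-robin into `k`
#' near-equal groups. Deterministic given the seed.
#'
#' @param subject_ids vector of subject identifiers (duplicates allowed;
#'   the unique set is partitioned).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return object of class `nf_fold_plan`: data.frame `subject`, `fold`.
#' @export
plan_folds <- function(subject_ids, k = 5, seed = 1) {
  subjects <- unique(subject_ids)
  if (length(subjects) < k)
    stop("need at least as many subjects as folds")
  ord <- with_seed(seed, sample(subjects))
  structure(data.frame(subject = ord,
                       fold = rep_len(seq_len(k), length(ord))),
            class = c("nf_fold_plan", "data.frame"))
}

#' Preprocess a cohort and cut it into windows
#'
#' Runs the conditioning chain on every session — EEG: zero-phase band-pass
#' 0.5-60 Hz + 58-62 Hz notch, average re-reference, optional bad-channel
#' interpolation; EDA: short-gap interpolation, zero-phase Butterworth
#' low-pass 1.9 Hz, optional tonic/phasic selection — then segments each
#' modality into non-overlapping labelled windows of the configured
#' lengths.
#'
#' @param cohort an `nf_cohort`.
#' @param config a [pipeline_config()].
#' @return list with `nf_windows` elements `eeg` and `eda`.
#' @export
prepare_windows <- function(cohort, config = pipeline_config()) {
  eeg_list <- list()
  eda_list <- list()
  for (s in cohort$sessions) {
    eeg <- average_rereference(eeg_filter(s$eeg))
    if (config$detect_bad) {
      mask <- detect_bad_channels(eeg)
      if (any(mask) && !all(mask)) eeg <- interpolate_channels(eeg, mask)
    }
    eda <- s$eda
    if (anyNA(eda$data)) {
      x <- interpolate_short_gaps(eda$data[1, ], eda$rate)
      long <- attr(x, "long_gap")
      x[long] <- NA # long gaps stay missing so their windows are dropped
      eda$data[1, ] <- x
    }
    na_mask <- is.na(eda$data[1, ])
    if (any(na_mask)) {
      filled <- eda$data[1, ]
      filled[na_mask] <- mean(filled, na.rm = TRUE)
      eda$data[1, ] <- filled
    }
    eda <- eda_filter(eda)
    if (config$eda_input != "conductance") {
      dec <- tonic_phasic(eda$data[1, ], eda$rate)
      eda$data[1, ] <- dec[[config$eda_input]]
    }
    if (any(na_mask)) eda$data[1, na_mask] <- NA
    eeg_list[[length(eeg_list) + 1]] <-
      segment_windows(eeg, config$eeg_window_s, config$label_threshold)
    eda_list[[length(eda_list) + 1]] <-
      segment_windows(eda, config$eda_window_s, config$label_threshold)
  }
  list(eeg = windows_bind(eeg_list), eda = windows_bind(eda_list))
}

evaluate_branch <- function(net, temp, rule, ws) {
  p <- calibrate_probs(net_logits(net, ws), temp)[, 2]
  compute_metrics(as.integer(p >= rule$tau), p, ws$y)
}

#' Run one cross-validation fold
#'
#' Fits [annoyance_fit()] on the windows of all subjects outside `fold` and
#' evaluates three branches on the untouched test fold: EEG-only, EDA-only,
#' and the deployed model (fusion if the validation gate passed, else the
#' EEG fallback). Any overlap between test subjects and training windows
#' raises an error.
#'
#' @param eeg,eda full `nf_windows` sets (unstandardized).
#' @param plan an [plan_folds()] plan.
#' @param fold fold number to hold out.
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return list with `metrics` (`eeg`, `eda`, `applied`), `gate`,
#'   `coefficients`, `fold`.
#' @export
run_fold <- function(eeg, eda, plan, fold, config = pipeline_config(),
                     verbose = FALSE) {
  test_subjects <- plan$subject[plan$fold == fold]
  is_test_e <- eeg$subject %in% test_subjects
  is_test_d <- eda$subject %in% test_subjects
  pool_e <- windows_subset(eeg, which(!is_test_e))
  pool_d <- windows_subset(eda, which(!is_test_d))
  if (length(intersect(unique(pool_e$subject), test_subjects)) ||
      length(intersect(unique(pool_d$subject), test_subjects)))
    stop("leakage: a test subject appears in the training pool")
  cfg <- config
  cfg$seed <- config$seed + fold
  fit <- annoyance_fit(pool_e, pool_d, cfg, verbose = verbose)

  test_e <- windows_subset(eeg, which(is_test_e), split = "test")
  test_d <- windows_subset(eda, which(is_test_d), split = "test")
  test_e_std <- apply_standardizer(test_e, fit$stats$eeg)
  test_d_std <- apply_standardizer(test_d, fit$stats$eda)

  m_eeg <- evaluate_branch(fit$nets$eeg, fit$temperatures$eeg,
                           fit$rules$eeg, test_e_std)
  m_eda <- evaluate_branch(fit$nets$eda, fit$temperatures$eda,
                           fit$rules$eda, test_d_std)
  m_applied <- if (config$fusion == "eda_only") {
    m_eda
  } else if (config$fusion == "eeg_only" || !identical(fit$gate, "use_fusion")) {
    m_eeg
  } else {
    pred <- predict(fit, test_e, test_d)
    compute_metrics(pred$class_applied, pred$p_applied, test_e$y)
  }
  list(fold = fold, metrics = list(eeg = m_eeg, eda = m_eda,
                                   applied = m_applied),
       gate = fit$gate, coefficients = coef(fit),
       best_epochs = c(eeg = fit$train_reports$eeg$best_epoch,
                       eda = fit$train_reports$eda$best_epoch))
}

#' Subject-grouped k-fold evaluation of the full pipeline
#'
#' Preprocesses the cohort (unless windows are supplied), plans
#' subject-grouped folds, runs [run_fold()] on each, and aggregates the
#' fold metrics (mean, CoV%, 95% CI) per branch.
#'
#' @param data an `nf_cohort`, or a list with `nf_windows` elements
#'   `eeg` and `eda` (as from [prepare_windows()]).
#' @param config a [pipeline_config()].
#' @param k number of folds.
#' @param seed seed for the fold plan.
#' @param verbose print progress.
#' @return object of class `nf_cv`: per-fold results, aggregates per
#'   branch, gate outcomes, the fold plan and config.
#' @export
run_cv <- function(data, config = pipeline_config(), k = 5, seed = 1,
                   verbose = FALSE) {
  windows <- if (inherits(data, "nf_cohort")) prepare_windows(data, config)
             else data
  plan <- plan_folds(windows$eeg$subject, k, seed)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    if (verbose) message("fold ", f, "/", k)
    folds[[f]] <- run_fold(windows$eeg, windows$eda, plan, f, config,
                           verbose = verbose)
  }
  get_branch <- function(b) lapply(folds, function(fr) fr$metrics[[b]])
  structure(list(
    folds = folds,
    aggregate = list(eeg = aggregate_folds(get_branch("eeg")),
                     eda = aggregate_folds(get_branch("eda")),
                     applied = aggregate_folds(get_branch("applied"))),
    gates = vapply(folds, function(fr) fr$gate, ""),
    plan = plan, config = config
  ), class = "nf_cv")
}

#' @export
print.nf_cv <- function(x, ...) {
  cat(sprintf("Subject-grouped %d-fold cross-validation (%s fusion)\n",
              length(x$folds), x$config$fusion))
  cat("gate outcomes:", paste(x$gates, collapse = ", "), "\n\n")
  for (b in names(x$aggregate)) {
    cat(toupper(b), "branch:\n")
    agg <- x$aggregate[[b]]
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-9s mean %.3f  CoV %5.2f%%  95%% CI [%.3f, %.3f]\n",
                  agg$metric[i], agg$mean[i], agg$cov_pct[i], agg$ci_lo[i],
                  agg$ci_hi[i]))
  }
  invisible(x)
}
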