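# pipeline configuration, the published baseline, and the ablation-informed
# optimal preset

#' Pipeline configuration
#'
#' All tunable fields of the end-to-end pipeline. The nine fields varied in
#' the ablation protocol are `fusion`, `batch_size`, `lr`, `eeg_window_s`,
#' `eda_window_s`, `weight_decay`, `l1_lambda`, `aug_k`, `val_fraction`;
#' the remaining fields control labelling, training schedule and
#' desk-scale reductions.
#'
#' @param fusion fusion strategy (`"stacked"`, `"weighted"`, `"gated"`,
#'   `"eeg_only"`, `"eda_only"`).
#' @param batch_size,lr,weight_decay,l1_lambda optimizer settings.
#' @param eeg_window_s,eda_window_s window lengths in seconds.
#' @param aug_k training-window duplication count (augmentation).
#' @param val_fraction fraction of training windows held out for
#'   validation (split 1:1 into calibration and fusion/threshold subsets).
#' @param label_threshold annoyance-rating cutoff for the high class.
#' @param aug_sd_max maximum augmentation noise SD.
#' @param max_epochs,patience,lr_factor,lr_patience training schedule
#'   (see [train_config()]).
#' @param max_train_windows optional stratified cap on training windows
#'   per fold (desk-scale runs); `NULL` = all.
#' @param eda_max_epochs optional separate epoch budget for the (much
#'   cheaper) EDA network; `NULL` uses `max_epochs`.
#' @param eda_input which EDA series feeds the LSTM: the low-pass
#'   `"conductance"`, or its `"phasic"` / `"tonic"` component.
#' @param detect_bad interpolate detected bad EEG channels during
#'   preprocessing.
#' @param threshold_objective `"macro"` or `"high"` (see
#'   [fit_threshold()]).
#' @param seed base seed; per-fold seeds are derived as `seed + fold`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fusion = "stacked", batch_size = 64, lr = 1e-3,
                            eeg_window_s = 2, eda_window_s = 20,
                            weight_decay = 1e-4, l1_lambda = 0, aug_k = 5,
                            val_fraction = 0.15, label_threshold = 7,
                            aug_sd_max = 0.10, max_epochs = 100,
                            patience = 50, lr_factor = 0.5, lr_patience = 10,
                            max_train_windows = NULL, eda_max_epochs = NULL,
                            eda_input = c("conductance", "phasic", "tonic"),
                            detect_bad = FALSE,
                            threshold_objective = c("macro", "high"),
                            seed = 1) {
  eda_input <- match.arg(eda_input)
  threshold_objective <- match.arg(threshold_objective)
  fusion <- match.arg(fusion, c("stacked", "weighted", "gated", "eeg_only",
                                "eda_only"))
  if (val_fraction <= 0 || val_fraction > 0.5)
    stop("'val_fraction' must lie in (0, 0.5]")
  structure(list(fusion = fusion, batch_size = as.integer(batch_size),
                 lr = lr, eeg_window_s = eeg_window_s,
                 eda_window_s = eda_window_s, weight_decay = weight_decay,
                 l1_lambda = l1_lambda, aug_k = as.integer(aug_k),
                 val_fraction = val_fraction,
                 label_threshold = label_threshold,
                 aug_sd_max = aug_sd_max,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 max_train_windows = max_train_windows,
                 eda_max_epochs = if (!is.null(eda_max_epochs))
                   as.integer(eda_max_epochs),
                 eda_input = eda_input, detect_bad = detect_bad,
                 threshold_objective = threshold_objective,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  fusion %s | batch %d | lr %g | EEG %g s | EDA %g s\n",
              x$fusion, x$batch_size, x$lr, x$eeg_window_s, x$eda_window_s))
  cat(sprintf("  wd %g | L1 %g | aug k=%d (sd<=%.2f) | val %.2f | seed %d\n",
              x$weight_decay, x$l1_lambda, x$aug_k, x$aug_sd_max,
              x$val_fraction, x$seed))
  invisible(x)
}

#' Baseline configuration
#'
#' The baseline pipeline settings: stacked fusion, batch 64, learning rate
#' 1e-3, 2 s EEG and 20 s EDA windows, weight decay 1e-4, no L1,
#' 5 augmentation duplications, 15% validation fraction.
#'
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
baseline_config <- function(...) {
  pipeline_config(...)
}

#' Ablation-informed optimal preset
#'
#' The configuration selected by the ablation study: stacked fusion,
#' batch size 32, learning rate 0.001, 6 s EEG windows, 5 s EDA windows,
#' weight decay 3e-5, L1 5e-6, 3 augmentation duplications, 20%
#' validation fraction.
#'
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
optimal_preset <- function(...) {
  pipeline_config(fusion = "stacked", batch_size = 32, lr = 0.001,
                  eeg_window_s = 6, eda_window_s = 5, weight_decay = 3e-5,
                  l1_lambda = 5e-6, aug_k = 3, val_fraction = 0.20, ...)
}
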