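# one-factor-at-a-time ablation harness
#
# Nine parameter groups, 44 runs in total; each run varies exactly one
# field of the baseline configuration (the grids include the baseline
# value of the varied field, as published).

ABLATION_GROUPS <- list(
  list(group = "fusion_strategy", field = "fusion",
       settings = list("stacked", "weighted", "gated", "eeg_only",
                       "eda_only")),
  list(group = "batch_size", field = "batch_size",
       settings = list(32, 48, 64, 96, 128, 256)),
  list(group = "learning_rate", field = "lr",
       settings = list(5e-4, 1e-3, 2e-3, 3e-3, 5e-3)),
  list(group = "eeg_window", field = "eeg_window_s",
       settings = list(1, 2, 4, 6, 8)),
  list(group = "eda_window", field = "eda_window_s",
       settings = list(5, 10, 15, 20, 30)),
  list(group = "weight_decay", field = "weight_decay",
       settings = list(0, 1e-5, 3e-5, 1e-4, 3e-4)),
  list(group = "l1_penalty", field = "l1_lambda",
       settings = list(0, 1e-6, 5e-6, 1e-5, 5e-5)),
  list(group = "augmentation", field = "aug_k",
       settings = list(3, 5, 7, 10)),
  list(group = "validation_fraction", field = "val_fraction",
       settings = list(0.10, 0.15, 0.20, 0.25))
)

#' Enumerate the ablation protocol
#'
#' Expands the nine-group, 44-run one-factor-at-a-time grid around a
#' baseline configuration: fusion strategy (5 runs), batch size (6),
#' learning rate (5), EEG window (5), EDA window (5), weight decay (5),
#' L1 penalty (5), augmentation factor (4), validation fraction (4).
#' Every run's configuration equals the baseline except (at most) the
#' varied field.
#'
#' @param baseline a [pipeline_config()] (default [baseline_config()]).
#' @return list of runs, each with `group`, `field`, `setting`, `config`.
#' @export
enumerate_ablation <- function(baseline = baseline_config()) {
  runs <- list()
  for (g in ABLATION_GROUPS)
    for (s in g$settings) {
      cfg <- baseline
      cfg[[g$field]] <- if (g$field %in% c("batch_size", "aug_k"))
        as.integer(s) else s
      runs[[length(runs) + 1]] <- list(group = g$group, field = g$field,
                                       setting = s, config = cfg)
    }
  runs
}

#' Run the ablation harness
#'
#' Executes [run_cv()] for each enumerated run on the same cohort (or
#' prepared windows) and returns one long-format row per
#' (run, branch, metric). Window-length runs re-segment the cohort, so an
#' `nf_cohort` input is required when those groups are included.
#'
#' @param cohort an `nf_cohort`.
#' @param runs runs from [enumerate_ablation()] (subset to taste).
#' @param k folds.
#' @param seed fold-plan seed.
#' @param verbose print progress.
#' @return data.frame: `group`, `setting`, `branch`, `metric`, `mean`,
#'   `cov_pct`, `ci_lo`, `ci_hi`.
#' @export
run_ablation <- function(cohort, runs = enumerate_ablation(), k = 5,
                         seed = 1, verbose = FALSE) {
  out <- list()
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (verbose)
      message(sprintf("ablation %d/%d: %s = %s", i, length(runs), r$group,
                      format(r$setting)))
    cv <- run_cv(cohort, r$config, k = k, seed = seed)
    for (b in names(cv$aggregate)) {
      agg <- cv$aggregate[[b]]
      agg$group <- r$group
      agg$setting <- as.character(r$setting)
      agg$branch <- b
      out[[length(out) + 1]] <- agg[, c("group", "setting", "branch",
                                        "metric", "mean", "cov_pct",
                                        "ci_lo", "ci_hi")]
    }
  }
  do.call(rbind, out)
}
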