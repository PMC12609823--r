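# evaluation protocol: metrics against independent oracles, fold planning,
# validation splitting, aggregation, ablation enumeration, optimal preset

test_that("perfect predictions score 1 on every metric", {
  y <- rep(0:1, 10)
  m <- compute_metrics(y, y, y)
  for (f in c("accuracy", "precision", "recall", "f1", "auroc", "auprc"))
    expect_equal(m[[f]], 1, info = f)
})

test_that("macro metrics match hand arithmetic on a printed toy matrix", {
  # TP = 3, FP = 1, FN = 2, TN = 4 (high = positive class)
  labels <- c(rep(1, 5), rep(0, 5))
  preds <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  scores <- ifelse(preds == 1, 0.9, 0.1)
  m <- compute_metrics(preds, scores, labels)
  expect_equal(m$confusion["high", "high"], 3)
  expect_equal(m$confusion["high", "normal"], 1)
  expect_equal(m$confusion["normal", "high"], 2)
  expect_equal(m$confusion["normal", "normal"], 4)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, (3 / 4 + 4 / 6) / 2)
  expect_equal(m$recall, (3 / 5 + 4 / 5) / 2)
  f1_hi <- 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5)
  f1_lo <- 2 * (4 / 6) * (4 / 5) / (4 / 6 + 4 / 5)
  expect_equal(m$f1, (f1_hi + f1_lo) / 2)
  # accuracy recomputed from the stored confusion matrix is consistent
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy,
               tolerance = 1e-12)
})

test_that("AUROC equals the pairwise-ordering statistic, ties at one half", {
  set.seed(1)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), sample(1:3, 1))
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    m <- compute_metrics(as.integer(scores >= 0.5), scores, labels)
    expect_equal(m$auroc, pairwise_auroc(scores, labels), tolerance = 1e-12)
  }
  # independent library cross-check
  set.seed(2)
  s <- runif(150)
  y <- rbinom(150, 1, 0.5)
  m <- compute_metrics(as.integer(s >= 0.5), s, y)
  expect_equal(m$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("random scores on balanced labels give chance-level AUROC", {
  set.seed(3)
  n <- 10000
  scores <- runif(n)
  labels <- rep(0:1, n / 2)
  m <- compute_metrics(as.integer(scores >= 0.5), scores, labels)
  expect_lt(abs(m$auroc - 0.5), 0.02)
  expect_warning(m1 <- compute_metrics(rep(1, 5), runif(5), rep(1, 5)),
                 "single-class")
  expect_true(is.na(m1$auroc) && is.na(m1$auprc))
})

test_that("fold aggregation computes mean, CoV and the t-based 95% CI", {
  mk <- function(v) lapply(v, function(a) list(accuracy = a, precision = a,
                                               recall = a, f1 = a, auroc = a,
                                               auprc = a))
  flat <- aggregate_folds(mk(rep(0.8, 5)))
  expect_equal(flat$mean, rep(0.8, 6))
  expect_equal(flat$cov_pct, rep(0, 6))
  expect_equal(flat$ci_lo, flat$ci_hi)
  three <- aggregate_folds(mk(c(0.7, 0.8, 0.9)))
  expect_equal(three$mean[1], 0.8)
  expect_equal(three$cov_pct[1], 12.5) # sd 0.1 / mean 0.8
  five <- aggregate_folds(mk(c(0.70, 0.75, 0.80, 0.85, 0.90)))
  s <- sd(c(0.70, 0.75, 0.80, 0.85, 0.90))
  expect_equal(five$ci_hi[1] - five$mean[1], 2.7764451 * s / sqrt(5),
               tolerance = 1e-6) # the k = 5 multiplier
  expect_equal(five$ci_hi[1] + five$ci_lo[1], 2 * five$mean[1]) # symmetric
  expect_error(aggregate_folds(mk(0.8)), "at least 2")
})

test_that("fold plans partition subjects into near-equal groups", {
  p25 <- plan_folds(rep(1:25, each = 6), k = 5, seed = 1)
  expect_equal(as.integer(table(p25$fold)), rep(5L, 5))
  expect_setequal(p25$subject, 1:25)
  p20 <- plan_folds(1:20, k = 5, seed = 1)
  expect_equal(as.integer(table(p20$fold)), rep(4L, 5))
  for (a in 1:4) for (b in (a + 1):5)
    expect_length(intersect(p20$subject[p20$fold == a],
                            p20$subject[p20$fold == b]), 0)
  expect_identical(plan_folds(1:25, 5, seed = 9), plan_folds(1:25, 5, seed = 9))
  expect_error(plan_folds(1:4, k = 5), "at least as many subjects")
})

test_that("validation split sizes and stratification behave as specified", {
  set.seed(4)
  labels <- c(rep(0L, 670), rep(1L, 330))
  sp <- split_validation(labels, 0.15, seed = 1)
  expect_length(sp$train, 850)
  expect_length(sp$cal, 75)
  expect_length(sp$fus, 75)
  expect_length(intersect(sp$cal, sp$fus), 0)
  expect_setequal(c(sp$train, sp$cal, sp$fus), seq_along(labels))
  for (part in sp) # label proportions within 2 points of the parent's
    expect_lt(abs(mean(labels[part]) - 0.33), 0.02)
  half <- split_validation(labels, 0.5, seed = 2)
  expect_length(half$cal, 250)
  expect_length(half$fus, 250)
  expect_warning(split_validation(c(rep(0L, 30), 1L), 0.2, seed = 3),
                 "stratify")
  expect_error(split_validation(labels, 0.6), "0, 0.5")
})

test_that("the ablation harness enumerates exactly the published 44 runs", {
  runs <- enumerate_ablation()
  expect_length(runs, 44)
  groups <- vapply(runs, `[[`, "", "group")
  expect_equal(as.integer(table(groups)[unique(groups)]),
               c(5L, 6L, 5L, 5L, 5L, 5L, 5L, 4L, 4L))
  batch <- sapply(runs[groups == "batch_size"], `[[`, "setting")
  expect_equal(unlist(batch), c(32, 48, 64, 96, 128, 256))
  # every run equals the baseline outside its varied field
  base <- baseline_config()
  for (r in runs) {
    other <- setdiff(c("fusion", "batch_size", "lr", "eeg_window_s",
                       "eda_window_s", "weight_decay", "l1_lambda", "aug_k",
                       "val_fraction"), r$field)
    for (f in other) expect_identical(r$config[[f]], base[[f]],
                                      info = paste(r$group, f))
    expect_true(isTRUE(all.equal(r$config[[r$field]], r$setting,
                                 check.attributes = FALSE)),
                info = paste(r$group, r$setting))
  }
})

test_that("the ablation runner reports long-format aggregates per run", {
  cohort <- generate_cohort(cohort_design(n_subjects = 6,
                                          session_length_s = 12, seed = 21))
  base <- baseline_config(eeg_window_s = 1, eda_window_s = 5, aug_k = 0,
                          max_epochs = 1, eda_max_epochs = 2,
                          max_train_windows = 100, seed = 2)
  runs <- Filter(function(r) r$setting %in% c("eeg_only", "eda_only"),
                 enumerate_ablation(base))
  res <- run_ablation(cohort, runs, k = 3, seed = 2)
  expect_setequal(unique(res$setting), c("eeg_only", "eda_only"))
  expect_setequal(unique(res$branch), c("eeg", "eda", "applied"))
  expect_equal(nrow(res), 2 * 3 * 6) # runs x branches x metrics
  expect_true(all(res$mean[res$metric == "accuracy"] >= 0 &
                    res$mean[res$metric == "accuracy"] <= 1))
})

test_that("the optimal preset pins every published value", {
  p <- optimal_preset()
  expect_identical(p$fusion, "stacked")
  expect_identical(p$batch_size, 32L)
  expect_equal(p$lr, 0.001)
  expect_equal(p$eeg_window_s, 6)
  expect_equal(p$eda_window_s, 5)
  expect_equal(p$weight_decay, 3e-5)
  expect_equal(p$l1_lambda, 5e-6)
  expect_identical(p$aug_k, 3L)
  expect_equal(p$val_fraction, 0.20)
  # differs from the baseline in 7 of the 9 ablation fields
  base <- baseline_config()
  fields <- c("fusion", "batch_size", "lr", "eeg_window_s", "eda_window_s",
              "weight_decay", "l1_lambda", "aug_k", "val_fraction")
  diffs <- sum(vapply(fields,
                      function(f) !isTRUE(all.equal(p[[f]], base[[f]])), TRUE))
  expect_equal(diffs, 7)
})
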