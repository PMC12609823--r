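# synthetic cohort generator: label design, seeded determinism, planted
# spectral/sudomotor effects, on-disk round trip

test_that("default label table reproduces the published per-condition counts", {
  lt <- default_label_table()
  expect_equal(nrow(lt), 150)
  expect_equal(anyDuplicated(paste(lt$subject, lt$noise_type, lt$level_db)), 0L)
  high <- function(nt, lv) sum(lt$rating[lt$noise_type == nt &
                                           lt$level_db == lv] > 7)
  expect_equal(high("earth_auger", 40), 1)
  expect_equal(high("earth_auger", 60), 5)
  expect_equal(high("earth_auger", 80), 20)
  expect_equal(high("pile_driver", 40), 2)
  expect_equal(high("pile_driver", 60), 4)
  expect_equal(high("pile_driver", 80), 17)
  # both common binarization cutoffs agree on the default ratings
  expect_identical(binarize_rating(lt$rating, 7), binarize_rating(lt$rating, 8))
})

test_that("session generation is reproducible and validates its inputs", {
  design <- cohort_design(n_subjects = 3, session_length_s = 5, seed = 9)
  meta <- list(subject = 2, noise_type = "pile_driver", level_db = 60)
  s1 <- generate_session(design, meta)
  s2 <- generate_session(design, meta)
  expect_identical(s1$eeg$data, s2$eeg$data)
  expect_identical(s1$eda$data, s2$eda$data)
  expect_false(anyNA(s1$eeg$data))
  expect_equal(ncol(s1$eeg$data), round(5 * 128))
  expect_equal(ncol(s1$eda$data), round(5 * 4))
  expect_error(generate_session(design, list(subject = 99,
                                             noise_type = "pile_driver",
                                             level_db = 60)),
               "not part of the cohort design")
})

test_that("planted theta effect raises frontal 4-8 Hz power in high sessions", {
  # >= 30 sessions per class, Welch-periodogram oracle on the raw signals
  lt <- default_label_table()
  design <- cohort_design(session_length_s = 10, theta_gain = 1.5,
                          alpha_gain = 1, subject_sd = 0.05, seed = 31)
  pow <- function(d) {
    vapply(seq_len(nrow(lt)), function(i) {
      s <- generate_session(d, lt[i, ])
      band_power(s$eeg$data["F3", ], 128, 4, 8)
    }, 0)
  }
  p <- pow(design)
  hi <- lt$rating > 7
  expect_gt(sum(hi), 30)
  expect_gt(mean(p[hi]) / mean(p[!hi]), 1.5) # ~ gain^2 = 2.25 planted
  # null design: class-conditional band powers equal within Monte-Carlo error
  null_design <- cohort_design(session_length_s = 10, theta_gain = 1,
                               alpha_gain = 1, scl_shift = 0,
                               scr_rate_normal = 3, scr_rate_high = 3,
                               subject_sd = 0.05, seed = 32)
  p0 <- pow(null_design)
  expect_lt(abs(mean(p0[hi]) / mean(p0[!hi]) - 1), 0.15)
})

test_that("planted effect gap grows monotonically with theta_gain", {
  lt <- default_label_table()
  hi <- lt$rating > 7
  gap <- vapply(c(1, 1.3, 1.6), function(g) {
    d <- cohort_design(session_length_s = 8, theta_gain = g, alpha_gain = 1,
                       subject_sd = 0.05, seed = 77)
    p <- vapply(seq_len(nrow(lt)), function(i) {
      s <- generate_session(d, lt[i, ])
      band_power(s$eeg$data["AF3", ], 128, 4, 8)
    }, 0)
    mean(p[hi]) - mean(p[!hi])
  }, 0)
  expect_true(all(diff(gap) > 0))
})

test_that("EDA carries the planted SCL shift and SCR-rate increase", {
  lt <- default_label_table()
  design <- cohort_design(session_length_s = 60, scl_shift = 0.5,
                          scr_rate_normal = 2, scr_rate_high = 8,
                          subject_sd = 0.02, seed = 55)
  idx <- seq_len(60)
  stats <- t(vapply(idx, function(i) {
    s <- generate_session(design, lt[i, ])
    x <- s$eda$data[1, ]
    dec <- tonic_phasic(x, 4)
    c(mean(x), mean(pmax(dec$phasic, 0)))
  }, c(0, 0)))
  hi <- lt$rating[idx] > 7
  expect_gt(mean(stats[hi, 1]) - mean(stats[!hi, 1]), 0.2) # tonic shift
  expect_gt(mean(stats[hi, 2]), mean(stats[!hi, 2]))       # more SCR mass
})

test_that("cohort generation, sizing, and manifest round trip", {
  design <- cohort_design(n_subjects = 2, session_length_s = 4, seed = 3)
  cohort <- generate_cohort(design)
  expect_equal(length(cohort$sessions), 12) # 2 subjects x 6 conditions
  expect_equal(nrow(cohort$labels), 12)
  dir <- file.path(tempdir(), "nf_cohort_test")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  for (f in c("n_subjects", "session_length_s", "eeg_rate", "eda_rate",
              "theta_gain", "alpha_gain", "scl_shift", "subject_sd",
              "noise_sd", "seed"))
    expect_equal(back$design[[f]], design[[f]], info = f)
  expect_equal(back$design$label_table$rating, design$label_table$rating)
  expect_equal(back$sessions[[1]]$eeg$data, cohort$sessions[[1]]$eeg$data,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("simulate() on a design delegates to the generator", {
  design <- cohort_design(n_subjects = 2, session_length_s = 2, seed = 5)
  c1 <- simulate(design, seed = 5)
  c2 <- generate_cohort(cohort_design(n_subjects = 2, session_length_s = 2,
                                      seed = 5))
  expect_identical(c1$sessions[[3]]$eeg$data, c2$sessions[[3]]$eeg$data)
})
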