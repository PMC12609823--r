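# windowing: label binarization, segmentation shapes, standardization,
# multimodal pairing, leakage safety

test_that("rating binarization follows the >7 rule and validates inputs", {
  expect_equal(binarize_rating(7), 0L)
  expect_equal(binarize_rating(8), 1L)
  expect_equal(binarize_rating(1), 0L)
  expect_equal(binarize_rating(8, threshold = 8), 0L)
  expect_error(binarize_rating(0), "1..10")
  expect_error(binarize_rating(11), "1..10")
})

test_that("segmentation yields floor(n/wT) windows with the contract shapes", {
  eeg <- make_recording(matrix(rnorm(14 * 660 * 128), 14), 128,
                        meta = list(subject = 1, rating = 9, session = "a",
                                    noise_type = "earth_auger", level_db = 80))
  ws <- segment_windows(eeg, 2)
  expect_equal(dim(ws$x), c(330, 14, 256))
  expect_true(all(ws$y == 1))
  expect_equal(ws$midpoint_s[1:3], c(1, 3, 5))
  eda <- make_recording(matrix(rnorm(660 * 4), 1), 4,
                        meta = list(subject = 1, rating = 4, session = "a",
                                    noise_type = "earth_auger", level_db = 40))
  wd <- segment_windows(eda, 20)
  expect_equal(dim(wd$x), c(33, 1, 80))
  short <- make_recording(matrix(rnorm(5 * 128), 1), 128,
                          meta = list(subject = 1, rating = 4, session = "a",
                                      noise_type = "earth_auger",
                                      level_db = 40))
  expect_warning(empty <- segment_windows(short, 10), "longer than session")
  expect_equal(dim(empty$x)[1], 0)
})

test_that("windows overlapping unrepaired gaps are dropped", {
  x <- matrix(rnorm(40), 1)
  x[1, 12] <- NA
  rec <- make_recording(x, 4, meta = list(subject = 1, rating = 4,
                                          session = "a",
                                          noise_type = "earth_auger",
                                          level_db = 40))
  ws <- segment_windows(rec, 2) # 8-sample windows; window 2 contains the NA
  expect_equal(dim(ws$x)[1], 4)
  expect_false(3 %in% round(ws$midpoint_s))
})

test_that("standardizer statistics match the population convention", {
  x <- array(0, c(1, 1, 2))
  x[1, 1, ] <- c(0, 2)
  ws <- make_windows(x, 0L)
  st <- fit_standardizer(ws)
  expect_equal(st$mean, 1)
  expect_equal(st$sd, 1) # population (ddof = 0) convention
  zeros <- make_windows(array(0, c(3, 2, 4)), rep(0L, 3))
  st0 <- fit_standardizer(zeros)
  expect_equal(st0$mean, c(0, 0))
  expect_equal(st0$sd, c(1e-8, 1e-8)) # degenerate floor
  set.seed(1)
  big <- make_windows(array(rnorm(10 * 2 * 8), c(10, 2, 8)), rep(0:1, 5))
  perm <- noisefuse:::windows_subset(big, sample(10))
  expect_equal(fit_standardizer(big), fit_standardizer(perm))
  expect_error(fit_standardizer(noisefuse:::windows_subset(big, integer(0))),
               "empty")
})

test_that("standardization detrends then scales by the training SD", {
  x <- array(0, c(2, 1, 2))
  x[1, 1, ] <- c(1, 3)  # detrend -> (-1, 1); / sd 2 -> (-0.5, 0.5)
  x[2, 1, ] <- c(4, 4)  # constant -> zeros regardless of stats
  ws <- make_windows(x, c(0L, 1L))
  out <- apply_standardizer(ws, list(mean = 1, sd = 2))
  expect_equal(out$x[1, 1, ], c(-0.5, 0.5))
  expect_equal(out$x[2, 1, ], c(0, 0))
  expect_error(apply_standardizer(ws, list(mean = c(0, 0), sd = c(1, 1))),
               "channel count")
  # pooled per-channel mean of a standardized training set is ~ 0
  set.seed(2)
  tr <- make_windows(array(rnorm(20 * 3 * 16, mean = 5), c(20, 3, 16)),
                     rep(0:1, 10))
  std <- apply_standardizer(tr, fit_standardizer(tr))
  expect_lt(max(abs(apply(std$x, 2, mean))), 1e-12)
})

test_that("standardizer depends only on the training split (no leakage)", {
  set.seed(3)
  full <- make_windows(array(rnorm(30 * 2 * 8), c(30, 2, 8)), rep(0:1, 15))
  train_idx <- 1:20
  st <- fit_standardizer(noisefuse:::windows_subset(full, train_idx))
  tampered <- full
  tampered$x[21:30, , ] <- 100 * tampered$x[21:30, , ] + 7
  st2 <- fit_standardizer(noisefuse:::windows_subset(tampered, train_idx))
  expect_identical(st, st2)
})

test_that("pairing matches containment and nearest-midpoint rules", {
  mk <- function(n, win, rate, session = "a", subject = 1) {
    make_windows(array(rnorm(n * 1 * (win * rate)), c(n, 1, win * rate)),
                 rep(0L, n), rate = rate, window_s = win,
                 session = rep(session, n), subject = rep(subject, n))
  }
  eeg <- mk(40, 2, 128)  # 0-80 s
  eda <- mk(4, 20, 4)    # 0-80 s
  p <- pair_windows(eeg, eda)
  expect_equal(nrow(p), 40)
  expect_equal(p$eda_idx, rep(1:4, each = 10)) # 10 EEG windows per EDA span
  same <- pair_windows(mk(5, 4, 128), mk(5, 4, 4))
  expect_equal(same$eda_idx, same$eeg_idx)     # aligned grids: identity
  tail <- pair_windows(mk(40, 2, 128), mk(3, 20, 4)) # EDA covers only 60 s
  expect_equal(tail$eda_idx[31:40], rep(3, 10))      # nearest = last window
  # pairing never crosses sessions; missing sessions dropped with warning
  eeg2 <- mk(4, 2, 128, session = "b", subject = 2)
  both_eda <- noisefuse:::windows_bind(list(eda, mk(2, 20, 4, "b", 2)))
  both_eeg <- noisefuse:::windows_bind(list(eeg, eeg2))
  p2 <- pair_windows(both_eeg, both_eda)
  expect_true(all(both_eeg$session[p2$eeg_idx] == both_eda$session[p2$eda_idx]))
  expect_warning(p3 <- pair_windows(both_eeg, eda), "missing")
  expect_equal(nrow(p3), 40)
})
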