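# signal conditioning: zero-phase filters, re-referencing, bad channels,
# gap interpolation, tonic-phasic decomposition

test_that("EEG filter removes DC, crushes 60 Hz, passes 10 Hz, keeps length", {
  rate <- 128
  t <- seq(0, 10, by = 1 / rate)[-1]
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq(2 * rate, 8 * rate) # avoid edge taper when measuring gain
  rec <- make_recording(rbind(rep(3, length(t)),          # constant offset
                              sin(2 * pi * 60 * t),       # line noise
                              sin(2 * pi * 10 * t)), rate)
  out <- eeg_filter(rec)
  expect_equal(dim(out$data), dim(rec$data))
  expect_lt(abs(mean(out$data[1, mid])), 0.01) # DC gain below -50 dB (power)
  expect_lt(rms(out$data[2, mid]) / rms(rec$data[2, mid]), 0.10)
  expect_lt(abs(rms(out$data[3, mid]) / rms(rec$data[3, mid]) - 1), 0.05)
  expect_error(eeg_filter(make_recording(rec$data, 100)), "Nyquist")
})

test_that("filtering is zero-phase: a symmetric pulse keeps its symmetry", {
  rate <- 128
  n <- 1024
  x <- exp(-((seq_len(n) - n / 2)^2) / (2 * 9))  # narrow Gaussian pulse
  rec <- make_recording(rbind(x, x), rate)
  y <- eeg_filter(rec)$data[1, ]
  cc <- vapply(-5:5, function(lag)
    sum(y[(6 + lag):(n - 6 + lag)] * x[6:(n - 6)]), 0)
  expect_equal(which.max(cc), 6) # cross-correlation peak at lag 0
  expect_equal(which.max(y), which.max(x))
})

test_that("average re-referencing zeroes the cross-channel mean", {
  x <- matrix(rnorm(14 * 100), 14, 100)
  out <- average_rereference(make_recording(x, 128))
  expect_true(all(abs(colMeans(out$data)) < 1e-10))
  two <- make_recording(rbind(rep(1, 50), rep(-1, 50)), 128)
  expect_equal(average_rereference(two)$data, two$data)
  v <- rnorm(60)
  same <- make_recording(rbind(v, v, v), 128)
  expect_true(all(abs(average_rereference(same)$data) < 1e-12))
  expect_error(average_rereference(make_recording(matrix(1, 1, 50), 128)),
               "2 channels")
})

test_that("bad-channel detection flags flatlines, variance outliers, and
           uncorrelated channels, and is permutation-equivariant", {
  set.seed(4)
  rate <- 128
  base <- band_noise(10 * rate, rate, 4, 30)
  x <- matrix(0, 14, 10 * rate)
  for (ch in 1:14) x[ch, ] <- base + 0.3 * rnorm(10 * rate)
  rec <- make_recording(x, rate)
  expect_false(any(detect_bad_channels(rec))) # clean homogeneous session
  flat <- rec
  flat$data[3, ] <- 0                         # whole-session flatline
  expect_true(detect_bad_channels(flat)[3])
  loud <- rec
  loud$data[7, ] <- loud$data[7, ] * 10       # 100x the others' variance
  mask <- detect_bad_channels(loud)
  expect_true(mask[7])
  expect_false(any(mask[-7]))
  lone <- rec
  lone$data[11, ] <- rnorm(10 * rate)         # uncorrelated with everyone
  expect_true(detect_bad_channels(lone)[11])
  perm <- sample(14)
  rec_p <- loud
  rec_p$data <- loud$data[perm, ]
  rec_p$channel_names <- loud$channel_names[perm]
  expect_identical(unname(detect_bad_channels(rec_p)), unname(mask[perm]))
})

test_that("inverse-distance interpolation reconstructs a neighborhood mean", {
  set.seed(11)
  rate <- 128
  pos <- electrode_positions()
  # smooth scalp topography: shared field plus modest channel-local noise
  # (the regime the inverse-distance surrogate is designed for)
  base <- rnorm(500)
  x <- t(vapply(1:14, function(ch) base + 0.4 * rnorm(500), numeric(500)))
  rownames(x) <- pos$channel
  rec <- make_recording(x, rate)
  # plant AF3 = mean of its 3 nearest neighbours, then flag and rebuild it
  d2 <- rowSums(sweep(as.matrix(pos[, 2:4]), 2,
                      as.numeric(pos[pos$channel == "AF3", 2:4]))^2)
  nn <- setdiff(order(d2), which(pos$channel == "AF3"))[1:3]
  truth <- colMeans(x[nn, ])
  rec$data[1, ] <- truth + 0.05 * rnorm(500)
  mask <- rep(FALSE, 14)
  mask[1] <- TRUE
  out <- interpolate_channels(rec, mask)
  expect_gt(cor(out$data[1, ], truth), 0.95)
  expect_identical(out$data[-1, ], rec$data[-1, ])
  expect_identical(interpolate_channels(rec, rep(FALSE, 14))$data, rec$data)
  expect_error(interpolate_channels(rec, rep(TRUE, 14)), "all channels")
})

test_that("EDA low-pass behaves in pass band and stop band", {
  rate <- 4
  t <- seq(0, 300, by = 1 / rate)[-1]
  const <- make_recording(matrix(2.5, 1, length(t)), rate)
  expect_equal(eda_filter(const)$data[1, ], const$data[1, ], tolerance = 1e-4)
  slow <- make_recording(matrix(sin(2 * pi * 0.05 * t), 1, length(t)), rate)
  out <- eda_filter(slow)
  mid <- seq(40, length(t) - 40)
  expect_lt(abs(sqrt(mean(out$data[1, mid]^2)) /
                  sqrt(mean(slow$data[1, mid]^2)) - 1), 0.05)
  set.seed(2)
  noise <- make_recording(matrix(rnorm(length(t)), 1, length(t)), rate)
  expect_lt(var(eda_filter(noise)$data[1, ]), var(noise$data[1, ]))
  expect_error(eda_filter(noise, cutoff = 2), "Nyquist")
})

test_that("short gaps are linearly interpolated, long gaps flagged", {
  x <- c(1, NA, 3, 5, 5, 5)
  out <- interpolate_short_gaps(x, rate = 4, max_gap_s = 2)
  expect_equal(out[2], 2)
  expect_false(any(attr(out, "long_gap")))
  clean <- interpolate_short_gaps(1:10 + 0, rate = 4)
  expect_equal(as.numeric(clean), 1:10 + 0)
  y <- c(1:4, rep(NA, 12), 5:8) # 3 s gap at 4 Hz > max 2 s
  out2 <- interpolate_short_gaps(y, rate = 4, max_gap_s = 2)
  expect_true(all(is.na(out2[5:16])))
  expect_true(all(attr(out2, "long_gap")[5:16]))
  expect_error(interpolate_short_gaps(rep(NA_real_, 5), 4), "entirely missing")
})

test_that("tonic-phasic decomposition conserves the signal exactly", {
  x <- cumsum(rnorm(400)) / 10 + 2
  dec <- tonic_phasic(x, rate = 4, window_s = 10)
  expect_lt(max(abs(dec$tonic + dec$phasic - x)), 1e-12)
  const <- tonic_phasic(rep(3.3, 100), rate = 4)
  expect_equal(const$tonic, rep(3.3, 100))
  expect_equal(const$phasic, rep(0, 100))
  # unit step mid-series, 4 Hz, 10 s window (41 samples, edge-truncated):
  # tonic at the step sample averages 21 post-step ones and 20 zeros
  step <- c(rep(0, 200), rep(1, 200))
  dec2 <- tonic_phasic(step, rate = 4, window_s = 10)
  expect_equal(dec2$tonic[201], 21 / 41)
  expect_error(tonic_phasic(rep(1, 10), rate = 4, window_s = 0.1),
               "window shorter")
})
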