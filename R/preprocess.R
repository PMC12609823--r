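# signal conditioning: zero-phase EEG band-pass + notch, average
# re-reference, bad-channel detection and interpolation, EDA Butterworth
# low-pass, short-gap interpolation, tonic-phasic decomposition

# Hamming FIR design via signal::fir1 with the order heuristic of the usual
# EEG tooling: band-pass transition width 25% of the lower edge, clamped to
# [2 Hz .. 2 x lower edge] (so a 0.5 Hz edge gets a 1 Hz transition and DC
# stays in the stopband); band-stop transition 25% of the stop width, at
# least 1 Hz. Order = 3.3 / normalized transition width, rounded up to even.
fir_design <- function(rate, band, type = c("pass", "stop")) {
  type <- match.arg(type)
  nyq <- rate / 2
  if (any(band >= nyq))
    stop(sprintf("filter band edge (%g Hz) must be below Nyquist (%g Hz)",
                 max(band), nyq))
  if (any(band <= 0)) stop("filter band edges must be positive")
  trans <- if (type == "pass") min(max(0.25 * min(band), 2), 2 * min(band))
           else max(0.25 * abs(diff(band)), 1)
  ord <- ceiling(3.3 * rate / trans)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, band / nyq, type)
}

# zero-phase filtering: forward-backward application of a linear-phase FIR
# equals filtering with the zero-phase response |H(w)|^2; applied spectrally
# with enough zero padding that the circular wrap only reads zeros
zero_phase_fir <- function(x, h) {
  n <- length(x)
  L <- length(h)
  nfft <- stats::nextn(n + 2 * L, 2)
  H2 <- Mod(fft(c(h, numeric(nfft - L))))^2
  Re(fft(fft(c(x, numeric(nfft - n))) * H2, inverse = TRUE))[1:n] / nfft
}

#' Zero-phase EEG filtering (band-pass + notch)
#'
#' Applies a zero-phase Hamming-window FIR band-pass (default 0.5-60 Hz)
#' followed by a zero-phase FIR band-stop notch (default stopband 58-62 Hz)
#' to every channel. Output length equals input length and DC/slow drift is
#' removed.
#'
#' @param rec an `nf_recording` (typically 128 Hz EEG).
#' @param band band-pass edges in Hz.
#' @param notch band-stop edges in Hz, or `NULL` to skip the notch.
#' @return filtered `nf_recording`.
#' @export
eeg_filter <- function(rec, band = c(0.5, 60), notch = c(58, 62)) {
  h_bp <- fir_design(rec$rate, band, "pass")
  h_bs <- if (!is.null(notch)) fir_design(rec$rate, notch, "stop") else NULL
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    x <- zero_phase_fir(rec$data[ch, ], h_bp)
    if (!is.null(h_bs)) x <- zero_phase_fir(x, h_bs)
    out$data[ch, ] <- x
  }
  out
}

#' Average re-referencing
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the cross-channel mean of the output is identically zero.
#'
#' @param rec an `nf_recording` with at least two channels.
#' @return re-referenced `nf_recording`.
#' @export
average_rereference <- function(rec) {
  if (nrow(rec$data) < 2)
    stop("average re-referencing needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Bad-channel criteria
#'
#' @param flatline_s minimum constant-run duration (s) to flag a flatline.
#' @param variance_z |z| threshold on the log-variance across channels.
#' @param neighbor_corr_min a channel whose maximum absolute correlation
#'   with every other channel falls below this is flagged.
#' @return list of class `bad_channel_criteria`.
#' @export
bad_channel_criteria <- function(flatline_s = 5, variance_z = 3,
                                 neighbor_corr_min = 0.1) {
  stopifnot_scalar(flatline_s, "flatline_s")
  if (!is.finite(variance_z) || !is.finite(neighbor_corr_min))
    stop("criteria must be finite")
  structure(list(flatline_s = flatline_s, variance_z = variance_z,
                 neighbor_corr_min = neighbor_corr_min),
            class = "bad_channel_criteria")
}

#' Detect bad EEG channels
#'
#' Flags a channel if it is constant for at least `flatline_s` seconds, OR
#' its log-variance is an outlier among channels (|z| > `variance_z`), OR
#' its maximum absolute correlation with any other channel is below
#' `neighbor_corr_min`.
#'
#' @param rec a filtered `nf_recording`.
#' @param criteria a [bad_channel_criteria()].
#' @return named logical vector, `TRUE` = flagged.
#' @export
detect_bad_channels <- function(rec, criteria = bad_channel_criteria()) {
  x <- rec$data
  nch <- nrow(x)
  flagged <- rep(FALSE, nch)
  names(flagged) <- rec$channel_names
  # (a) flatline: longest run of zero first-difference
  min_run <- criteria$flatline_s * rec$rate
  for (ch in seq_len(nch)) {
    d <- diff(x[ch, ]) == 0
    if (any(d)) {
      r <- rle(d)
      if (max(r$lengths[r$values]) + 1 >= min_run) flagged[ch] <- TRUE
    }
  }
  # (b) abnormal variance (z-score of log-variance among channels)
  v <- apply(x, 1, stats::var)
  lv <- log(pmax(v, .Machine$double.xmin))
  z <- (lv - mean(lv)) / max(sd(lv), 1e-12)
  flagged <- flagged | abs(z) > criteria$variance_z
  # (c) low correlation with all other channels
  if (nch >= 3) {
    cc <- abs(suppressWarnings(cor(t(x))))
    diag(cc) <- NA
    maxcor <- suppressWarnings(apply(cc, 1, max, na.rm = TRUE))
    maxcor[!is.finite(maxcor)] <- 0
    flagged <- flagged | maxcor < criteria$neighbor_corr_min
  } else {
    warning("fewer than 3 channels: correlation criterion skipped")
  }
  flagged
}

#' Packaged 10-20 electrode coordinates
#'
#' Unit-sphere (x, y, z) coordinates for the 14-channel montage, used by
#' [interpolate_channels()].
#'
#' @return data.frame with columns `channel`, `x`, `y`, `z`.
#' @export
electrode_positions <- function() {
  path <- system.file("extdata", "electrode_positions_1020.csv",
                      package = "noisefuse")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Interpolate flagged channels
#'
#' Replaces each flagged channel by an inverse-distance-weighted (power 2)
#' combination of the unflagged channels on the unit-sphere montage — a
#' light-weight surrogate for spherical-spline interpolation (the two agree
#' closely on smooth scalp topographies; see the methods vignette).
#'
#' @param rec an `nf_recording`.
#' @param mask logical vector of flagged channels.
#' @param positions electrode coordinates as from [electrode_positions()].
#' @return `nf_recording` with flagged channels replaced.
#' @export
interpolate_channels <- function(rec, mask, positions = electrode_positions()) {
  if (!any(mask)) return(rec)
  if (all(mask)) stop("all channels flagged: nothing to interpolate from")
  pos <- positions[match(rec$channel_names, positions$channel), c("x", "y", "z")]
  if (anyNA(pos)) stop("positions missing for some channels")
  pos <- as.matrix(pos)
  good <- which(!mask)
  for (ch in which(mask)) {
    d2 <- rowSums(sweep(pos[good, , drop = FALSE], 2, pos[ch, ])^2)
    w <- 1 / pmax(d2, 1e-12)
    w <- w / sum(w)
    rec$data[ch, ] <- drop(w %*% rec$data[good, , drop = FALSE])
  }
  rec
}

#' Zero-phase EDA low-pass filter
#'
#' 4th-order Butterworth low-pass (default cutoff 1.9 Hz at 4 Hz sampling),
#' applied forward-backward with [signal::filtfilt()].
#'
#' @param rec an `nf_recording` (univariate EDA).
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order.
#' @return filtered `nf_recording`.
#' @export
eda_filter <- function(rec, cutoff = 1.9, order = 4) {
  nyq <- rec$rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, "low")
  out <- rec
  n <- ncol(rec$data)
  pad <- min(24 * (order + 1), n - 1) # odd-reflection padding kills the
  for (ch in seq_len(nrow(rec$data))) {          # filtfilt edge transient
    x <- rec$data[ch, ]
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    out$data[ch, ] <- signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  }
  out
}

#' Linear interpolation of short gaps
#'
#' `NA` runs no longer than `max_gap_s` are linearly interpolated from the
#' flanking samples. Longer runs (and edge runs without both flanks) are
#' left as `NA` and reported in the `"long_gap"` attribute so the windowing
#' stage can drop the affected windows.
#'
#' @param x numeric series with `NA` marking gaps.
#' @param rate sampling rate in Hz.
#' @param max_gap_s maximum interpolatable gap duration in seconds.
#' @return the series with short gaps filled; attribute `"long_gap"` is a
#'   logical vector marking samples still missing.
#' @export
interpolate_short_gaps <- function(x, rate, max_gap_s = 2) {
  if (all(is.na(x))) stop("series is entirely missing")
  na <- is.na(x)
  if (!any(na)) {
    attr(x, "long_gap") <- rep(FALSE, length(x))
    return(x)
  }
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  long <- rep(FALSE, length(x))
  max_run <- max_gap_s * rate
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    interior <- s > 1 && e < length(x)
    if (r$lengths[i] <= max_run && interior) {
      x[s:e] <- approx(c(s - 1, e + 1), c(x[s - 1], x[e + 1]), s:e)$y
    } else {
      long[s:e] <- TRUE
    }
  }
  attr(x, "long_gap") <- long
  x
}

#' Tonic-phasic decomposition of skin conductance
#'
#' The tonic level is a centered moving average over `window_s` seconds
#' (window truncated, not padded, at the series edges); the phasic
#' component is the residual, so `tonic + phasic` reconstructs the input
#' exactly.
#'
#' @param x numeric conductance series (uS scale), finite.
#' @param rate sampling rate in Hz.
#' @param window_s moving-average window in seconds (default 10).
#' @return list with `tonic`, `phasic`, `window_s`.
#' @export
tonic_phasic <- function(x, rate, window_s = 10) {
  if (any(!is.finite(x))) stop("series must be finite")
  half <- floor(window_s * rate / 2)
  if (2 * half + 1 < 1 || window_s * rate < 1)
    stop("window shorter than one sample")
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  tonic <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  list(tonic = tonic, phasic = x - tonic, window_s = window_s)
}
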