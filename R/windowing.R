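# windowing: binary labels, non-overlapping segmentation, leakage-safe
# standardization, multimodal pairing
#
# A window set stores tensors as an (n, channels, T) array together with
# binary labels and subject/session provenance. EEG windows have
# T = round(128 * window_s); EDA windows T = round(4 * window_s).

new_window_set <- function(modality, window_s, rate, x, y, subject, session,
                           midpoint_s, stats = NULL, split = NULL) {
  structure(list(modality = modality, window_s = window_s, rate = rate,
                 x = x, y = y, subject = subject, session = session,
                 midpoint_s = midpoint_s, stats = stats, split = split),
            class = "nf_windows")
}

#' @export
print.nf_windows <- function(x, ...) {
  cat(sprintf("<nf_windows> %s: %d windows of %d ch x %d samples (%g s @ %g Hz)\n",
              x$modality, dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$window_s,
              x$rate))
  cat(sprintf("  %d high / %d normal; %d subjects%s\n", sum(x$y == 1),
              sum(x$y == 0), length(unique(x$subject)),
              if (!is.null(x$split)) paste0("; split=", x$split) else ""))
  invisible(x)
}

n_windows <- function(ws) dim(ws$x)[1]

windows_subset <- function(ws, idx, split = ws$split) {
  new_window_set(ws$modality, ws$window_s, ws$rate,
                 ws$x[idx, , , drop = FALSE], ws$y[idx], ws$subject[idx],
                 ws$session[idx], ws$midpoint_s[idx], ws$stats, split)
}

windows_bind <- function(ws_list) {
  ws_list <- ws_list[vapply(ws_list, function(w) n_windows(w) > 0, TRUE)]
  if (!length(ws_list)) stop("no windows to combine")
  w1 <- ws_list[[1]]
  ns <- vapply(ws_list, n_windows, 0L)
  x <- array(0, c(sum(ns), dim(w1$x)[2], dim(w1$x)[3]))
  at <- 0L
  for (w in ws_list) {
    n <- n_windows(w)
    if (n) x[(at + 1):(at + n), , ] <- w$x
    at <- at + n
  }
  new_window_set(w1$modality, w1$window_s, w1$rate, x,
                 unlist(lapply(ws_list, `[[`, "y")),
                 unlist(lapply(ws_list, `[[`, "subject")),
                 unlist(lapply(ws_list, `[[`, "session")),
                 unlist(lapply(ws_list, `[[`, "midpoint_s")))
}

#' Binarize an annoyance rating
#'
#' Ratings above `threshold` map to 1 (high annoyance), all others to 0.
#' The default threshold 7 matches the package's labelling convention;
#' 8 reproduces the stricter definition used in earlier comparison work.
#'
#' @param rating integer rating(s) in 1..10.
#' @param threshold cutoff; `rating > threshold` is high.
#' @return integer vector of 0/1 labels.
#' @export
binarize_rating <- function(rating, threshold = 7) {
  if (any(rating < 1 | rating > 10))
    stop("ratings must lie in 1..10")
  as.integer(rating > threshold)
}

#' Segment a recording into non-overlapping windows
#'
#' Cuts the session into `floor(samples / (window_s * rate))` consecutive
#' non-overlapping windows (the incomplete tail is discarded). Each window
#' carries the session's binary label and its midpoint time. Windows that
#' overlap unrepaired gaps (`NA` samples) are dropped.
#'
#' @param rec an `nf_recording`.
#' @param window_s window length in seconds.
#' @param label_threshold rating cutoff passed to [binarize_rating()].
#' @return an `nf_windows` set (possibly empty, with a warning, if the
#'   window is longer than the session).
#' @export
segment_windows <- function(rec, window_s, label_threshold = 7) {
  w <- round(window_s * rec$rate)
  if (w < 1) stop("window must cover at least one sample")
  n <- ncol(rec$data)
  k <- floor(n / w)
  modality <- if (nrow(rec$data) > 1) "EEG" else "EDA"
  y <- binarize_rating(rec$meta$rating, label_threshold)
  if (k == 0) {
    warning("window (", window_s, " s) longer than session: no windows")
    return(new_window_set(modality, window_s, rec$rate,
                          array(0, c(0, nrow(rec$data), w)), integer(0),
                          integer(0), character(0), numeric(0)))
  }
  x <- array(0, c(k, nrow(rec$data), w))
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    seg <- rec$data[, ((i - 1) * w + 1):(i * w), drop = FALSE]
    if (anyNA(seg)) keep[i] <- FALSE else x[i, , ] <- seg
  }
  mid <- (seq_len(k) - 0.5) * w / rec$rate
  ws <- new_window_set(modality, window_s, rec$rate, x,
                       rep(y, k), rep(rec$meta$subject, k),
                       rep(rec$meta$session, k), mid)
  if (!all(keep)) ws <- windows_subset(ws, which(keep))
  ws
}

#' Fit standardization statistics on a training split
#'
#' Per-channel mean and standard deviation pooled over all training windows
#' and time points (population SD, floored at 1e-8).
#'
#' @param train an `nf_windows` training set.
#' @return list with `mean` and `sd` vectors (one entry per channel).
#' @export
fit_standardizer <- function(train) {
  if (n_windows(train) == 0) stop("cannot fit a standardizer on an empty set")
  nc <- dim(train$x)[2]
  mu <- numeric(nc)
  sdv <- numeric(nc)
  for (c in seq_len(nc)) {
    v <- train$x[, c, ]
    mu[c] <- mean(v)
    sdv[c] <- max(sqrt(mean((v - mu[c])^2)), 1e-8)
  }
  list(mean = mu, sd = sdv)
}

#' Apply standardization to a window set
#'
#' Each window is first detrended (its own per-channel mean removed) and
#' then scaled by the training standard deviation; the training mean is
#' absorbed by the detrend step. Channel counts must match.
#'
#' @param ws an `nf_windows`.
#' @param stats statistics from [fit_standardizer()].
#' @return standardized `nf_windows` (with `stats` recorded).
#' @export
apply_standardizer <- function(ws, stats) {
  nc <- dim(ws$x)[2]
  if (length(stats$mean) != nc || length(stats$sd) != nc)
    stop("standardizer channel count does not match the window set")
  for (c in seq_len(nc)) {
    v <- array(ws$x[, c, , drop = FALSE], c(dim(ws$x)[1], dim(ws$x)[3]))
    ws$x[, c, ] <- (v - rowMeans(v)) / stats$sd[c]
  }
  ws$stats <- stats
  ws
}

#' Pair EEG windows with same-session EDA windows
#'
#' Each EEG window is paired with the EDA window of the same session whose
#' time span contains the EEG window's midpoint; if no span contains it
#' (e.g. the EDA tail was discarded), the EDA window with the nearest
#' midpoint is used. EEG windows from sessions absent in the EDA set are
#' dropped with a warning. Pairs never cross sessions or subjects, and
#' paired labels always agree.
#'
#' @param eeg,eda `nf_windows` sets of the two modalities.
#' @return data.frame with columns `eeg_idx`, `eda_idx`.
#' @export
pair_windows <- function(eeg, eda) {
  out_e <- integer(0)
  out_d <- integer(0)
  missing_sessions <- setdiff(unique(eeg$session), unique(eda$session))
  if (length(missing_sessions))
    warning("sessions missing in EDA set, their EEG windows dropped: ",
            paste(missing_sessions, collapse = ", "))
  for (s in intersect(unique(eeg$session), unique(eda$session))) {
    ie <- which(eeg$session == s)
    id <- which(eda$session == s)
    half <- eda$window_s / 2
    for (i in ie) {
      m <- eeg$midpoint_s[i]
      inside <- which(abs(eda$midpoint_s[id] - m) <= half)
      j <- if (length(inside)) id[inside[1]]
           else id[which.min(abs(eda$midpoint_s[id] - m))]
      out_e <- c(out_e, i)
      out_d <- c(out_d, j)
    }
  }
  data.frame(eeg_idx = out_e, eda_idx = out_d)
}
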