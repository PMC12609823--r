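# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# band-limited unit-variance Gaussian noise via frequency-domain synthesis:
# complex-Gaussian spectrum restricted to [f_lo, f_hi], inverse FFT
band_noise <- function(n, rate, f_lo, f_hi) {
  m <- floor((n - 1) / 2)
  freq <- (1:m) * rate / n
  mask <- freq >= f_lo & freq <= f_hi
  spec <- complex(real = rnorm(m), imaginary = rnorm(m)) * mask
  full <- rep(0 + 0i, n)
  full[2:(m + 1)] <- spec
  full[n:(n - m + 1)] <- Conj(spec)
  if (n %% 2 == 0) {
    f_nyq <- rate / 2
    if (f_nyq >= f_lo && f_nyq <= f_hi)
      full[n / 2 + 1] <- complex(real = rnorm(1), imaginary = 0)
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

# row-wise softmax of an n x 2 logit matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Welch-averaged band power
#'
#' Average power of `x` in the frequency band `[f_lo, f_hi]`, estimated by
#' averaging Hann-tapered periodograms over non-overlapping segments
#' (Welch's method). Used to verify planted spectral effects in synthetic
#' EEG.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz.
#' @param seg_len segment length in samples (default 256).
#' @return mean power (signal-units squared) in the band.
#' @export
band_power <- function(x, rate, f_lo, f_hi, seg_len = 256) {
  n <- length(x)
  nseg <- floor(n / seg_len)
  if (nseg < 1) {
    seg_len <- n
    nseg <- 1
  }
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  u <- mean(win^2)
  freq <- (seq_len(seg_len) - 1) * rate / seg_len
  keep <- freq >= f_lo & freq <= f_hi & freq <= rate / 2
  psd <- rep(0, seg_len)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    seg <- (seg - mean(seg)) * win
    psd <- psd + Mod(fft(seg))^2 / (seg_len * u)
  }
  psd <- psd / nseg
  mean(psd[keep]) / seg_len
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (positive && x <= 0))
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
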