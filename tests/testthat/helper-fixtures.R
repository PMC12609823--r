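# shared fixture builders (all data is generated in code)

# a window set built directly from raw tensors
make_windows <- function(x, y, modality = "EEG", rate = 128,
                         window_s = dim(x)[3] / rate,
                         subject = rep(1L, dim(x)[1]),
                         session = rep("s1", dim(x)[1]),
                         midpoint_s = (seq_len(dim(x)[1]) - 0.5) * window_s,
                         split = NULL) {
  noisefuse:::new_window_set(modality, window_s, rate, x, y, subject,
                             session, midpoint_s, split = split)
}

# gaussian-noise windows with a class-dependent constant pattern: an easy,
# linearly separable two-class problem for training sanity checks
toy_separable_windows <- function(n = 60, C = 14, T = 16, shift = 2,
                                  seed = 7, split = "train") {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  pattern <- matrix(rnorm(C * T), C, T)
  x <- array(rnorm(n * C * T, sd = 0.5), c(n, C, T))
  for (i in which(y == 1)) x[i, , ] <- x[i, , ] + shift * pattern
  make_windows(x, y, split = split)
}

# a small recording wrapper
make_recording <- function(data, rate, meta = list(subject = 1L,
                                                   noise_type = "earth_auger",
                                                   level_db = 40, rating = 4,
                                                   session = "s1")) {
  noisefuse:::new_recording(data, rate,
                            rownames(data) %||% paste0("ch", seq_len(nrow(data))),
                            meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force F1-optimal threshold: evaluates every cut that can matter
# (all observed scores, midpoints, and the endpoints) and returns the best
# achievable F1 -- independent oracle for fit_threshold
brute_force_best_f1 <- function(scores, labels, objective = "macro") {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, u, 1, (u[-1] + u[-length(u)]) / 2,
                        pmax(u - 1e-9, 0), pmin(u + 1e-9, 1))))
  max(vapply(cand, function(tau)
    noisefuse:::f1_at(scores, labels, tau, objective), 0))
}

# brute-force AUROC: fraction of correctly ordered (high, normal) pairs,
# ties counting one half
pairwise_auroc <- function(scores, labels) {
  hi <- scores[labels == 1]
  lo <- scores[labels == 0]
  tot <- 0
  for (a in hi) tot <- tot + sum(a > lo) + 0.5 * sum(a == lo)
  tot / (length(hi) * length(lo))
}
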