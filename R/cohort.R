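# synthetic multimodal cohort generator
#
# Emulates the laboratory design the classifier was built for: 25 subjects,
# 6 sessions each (noise type {earth auger, pile driver} x level {40,60,80}
# dBA), 14-channel EEG at 128 Hz and univariate EDA at 4 Hz, with per-session
# 1-10 annoyance ratings following the published per-condition assignment.
# High-annoyance sessions carry elevated frontal theta power, reduced alpha
# power, a tonic skin-conductance (SCL) offset and a higher skin-conductance
# response (SCR) rate.

EEG_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                  "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
FRONTAL_CHANNELS <- c("AF3", "AF4", "F3", "F4", "F7", "F8")
NOISE_TYPES <- c("earth_auger", "pile_driver")
NOISE_LEVELS <- c(40, 60, 80)

# EEG rhythm bands and their baseline RMS amplitudes (arbitrary microvolt
# scale); the planted class effects multiply theta (frontal) and alpha (all)
EEG_BANDS <- list(
  delta = list(band = c(1, 4), amp = 4),
  theta = list(band = c(4, 8), amp = 5),
  alpha = list(band = c(8, 13), amp = 8),
  beta = list(band = c(13, 30), amp = 3)
)

#' Published per-condition annoyance label assignment
#'
#' Returns the 150-row (25 subjects x 2 noise types x 3 levels) annoyance
#' rating table used as the default label design of the synthetic cohort.
#' Subjects reported as highly annoyed in a condition receive `high_rating`
#' (> 7 so that both common binarization cutoffs, 7 and 8, agree) and all
#' others `normal_rating`. Per-condition counts of high-annoyance subjects
#' are 1/5/20 (earth auger at 40/60/80 dBA) and 2/4/17 (pile driver).
#'
#' @param high_rating rating given to high-annoyance entries (default 9).
#' @param normal_rating rating given to normal-annoyance entries (default 4).
#' @return data.frame with columns `subject`, `noise_type`, `level_db`,
#'   `rating`.
#' @export
default_label_table <- function(high_rating = 9, normal_rating = 4) {
  if (!(high_rating %in% 1:10) || !(normal_rating %in% 1:10))
    stop("ratings must be integers in 1..10")
  high_sets <- list(
    earth_auger = list(
      `40` = 10,
      `60` = c(10, 15, 16, 23, 25),
      `80` = setdiff(1:25, c(3, 8, 19, 20, 21))
    ),
    pile_driver = list(
      `40` = c(10, 23),
      `60` = c(9, 10, 14, 23),
      `80` = setdiff(1:25, c(3, 6, 7, 13, 14, 16, 17, 18))
    )
  )
  rows <- list()
  for (nt in NOISE_TYPES)
    for (lv in NOISE_LEVELS) {
      hi <- high_sets[[nt]][[as.character(lv)]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = 1:25, noise_type = nt, level_db = lv,
        rating = ifelse(1:25 %in% hi, high_rating, normal_rating)
      )
    }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$noise_type, out$level_db), ]
  rownames(out) <- NULL
  out
}

#' Synthetic cohort design
#'
#' Bundles every parameter of the synthetic multimodal cohort: geometry
#' (subjects, session length, sampling rates, channel count), the label
#' design, the planted class effects and their sizes, between-subject
#' variability, sensor noise, and the master seed.
#'
#' Effect-size parameters: `theta_gain` multiplies the theta-band RMS on
#' frontal channels of high-annoyance sessions (>= 1), `alpha_gain`
#' multiplies the alpha-band RMS on all channels (<= 1), `scl_shift` (uS)
#' raises the tonic skin-conductance level, and `scr_rate_high` /
#' `scr_rate_normal` (events per minute) set the Poisson rate of phasic
#' skin-conductance responses per class.
#'
#' @param n_subjects number of subjects (<= 25; subsets the label table).
#' @param session_length_s session duration in seconds (default 660,
#'   i.e. about 11 minutes; reduce for fast experiments).
#' @param eeg_rate,eda_rate sampling rates in Hz.
#' @param n_eeg_channels number of EEG channels (14 for the default montage).
#' @param label_table data.frame as from [default_label_table()].
#' @param label_threshold ratings above this are "high annoyance".
#' @param theta_gain,alpha_gain,scl_shift,scr_rate_normal,scr_rate_high
#'   planted effect sizes (see Details).
#' @param subject_sd log-scale SD of per-subject amplitude random effects.
#' @param noise_sd EEG white sensor-noise SD (uV scale).
#' @param eda_noise_sd EDA sensor-noise SD (uS scale).
#' @param seed master seed; every session derives its own stream from it.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 25, session_length_s = 660,
                          eeg_rate = 128, eda_rate = 4, n_eeg_channels = 14,
                          label_table = default_label_table(),
                          label_threshold = 7,
                          theta_gain = 1.4, alpha_gain = 0.75,
                          scl_shift = 0.3, scr_rate_normal = 3,
                          scr_rate_high = 6, subject_sd = 0.1,
                          noise_sd = 2, eda_noise_sd = 0.02, seed = 1) {
  stopifnot_scalar(session_length_s, "session_length_s")
  stopifnot_scalar(eeg_rate, "eeg_rate")
  stopifnot_scalar(eda_rate, "eda_rate")
  if (n_eeg_channels != 14)
    stop("the default montage has 14 EEG channels")
  if (theta_gain < 1) stop("'theta_gain' must be >= 1")
  if (alpha_gain > 1) stop("'alpha_gain' must be <= 1")
  if (scl_shift < 0) stop("'scl_shift' must be >= 0")
  if (scr_rate_high < scr_rate_normal)
    stop("'scr_rate_high' must be >= 'scr_rate_normal'")
  if (n_subjects < 1 || n_subjects > max(label_table$subject))
    stop("'n_subjects' outside the label table's subject range")
  lt <- label_table[label_table$subject <= n_subjects, , drop = FALSE]
  key <- paste(lt$subject, lt$noise_type, lt$level_db)
  if (anyDuplicated(key))
    stop("label table must cover each (subject, noise type, level) once")
  if (nrow(lt) != n_subjects * length(NOISE_TYPES) * length(NOISE_LEVELS))
    stop("label table must cover every (subject, noise type, level) combination")
  if (!all(lt$rating %in% 1:10)) stop("ratings must lie in 1..10")
  structure(list(
    n_subjects = n_subjects,
    sessions_per_subject = length(NOISE_TYPES) * length(NOISE_LEVELS),
    session_length_s = session_length_s,
    eeg_rate = eeg_rate, eda_rate = eda_rate,
    n_eeg_channels = n_eeg_channels,
    label_table = lt, label_threshold = label_threshold,
    theta_gain = theta_gain, alpha_gain = alpha_gain,
    scl_shift = scl_shift, scr_rate_normal = scr_rate_normal,
    scr_rate_high = scr_rate_high, subject_sd = subject_sd,
    noise_sd = noise_sd, eda_noise_sd = eda_noise_sd, seed = seed
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Synthetic EEG+EDA cohort design\n")
  cat(sprintf("  %d subjects x %d sessions, %.0f s each\n", x$n_subjects,
              x$sessions_per_subject, x$session_length_s))
  cat(sprintf("  EEG: %d ch @ %g Hz; EDA: 1 ch @ %g Hz\n",
              x$n_eeg_channels, x$eeg_rate, x$eda_rate))
  cat(sprintf("  effects: theta x%.2f (frontal), alpha x%.2f, SCL +%.2f uS, SCR %g vs %g /min\n",
              x$theta_gain, x$alpha_gain, x$scl_shift, x$scr_rate_high,
              x$scr_rate_normal))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

session_index <- function(design, meta) {
  lt <- design$label_table
  idx <- which(lt$subject == meta$subject &
                 lt$noise_type == meta$noise_type &
                 lt$level_db == meta$level_db)
  if (length(idx) != 1)
    stop("session (subject ", meta$subject, ", ", meta$noise_type, ", ",
         meta$level_db, " dBA) is not part of the cohort design")
  idx
}

# per-subject lognormal amplitude multipliers, reproducible from the design
subject_effects <- function(design, subject) {
  with_seed(design$seed + 500000L + as.integer(subject), {
    list(
      band_mult = exp(rnorm(length(EEG_BANDS), 0, design$subject_sd)),
      eda_mult = exp(rnorm(1, 0, design$subject_sd))
    )
  })
}

new_recording <- function(data, rate, channel_names, meta) {
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 meta = meta), class = "nf_recording")
}

#' @export
print.nf_recording <- function(x, ...) {
  cat(sprintf("<nf_recording> %d ch x %d samples @ %g Hz", nrow(x$data),
              ncol(x$data), x$rate))
  if (!is.null(x$meta))
    cat(sprintf("  [subject %s, %s, %s dBA, rating %s]", x$meta$subject,
                x$meta$noise_type, x$meta$level_db, x$meta$rating))
  cat("\n")
  invisible(x)
}

#' Generate one synthetic EEG+EDA session
#'
#' EEG channels are sums of band-limited Gaussian processes
#' (delta/theta/alpha/beta) plus white sensor noise; in high-annoyance
#' sessions the frontal theta amplitude is multiplied by `theta_gain` and
#' alpha (all channels) by `alpha_gain`. EDA is a slow tonic level (plus
#' `scl_shift` for high annoyance) with Poisson-timed phasic SCRs
#' (1 s rise, 3 s exponential decay) at the class-dependent rate, plus
#' sensor noise. Per-subject lognormal amplitude effects shift baselines.
#' Fully reproducible: the session's RNG stream is derived from the design
#' seed and the session's position in the label table.
#'
#' @param design a [cohort_design()].
#' @param meta list with `subject`, `noise_type`, `level_db` (must be a row
#'   of the design's label table); `rating` is taken from the table.
#' @return list with elements `eeg` and `eda`, each an `nf_recording`.
#' @export
generate_session <- function(design, meta) {
  idx <- session_index(design, meta)
  lt <- design$label_table[idx, ]
  meta <- list(subject = lt$subject, noise_type = lt$noise_type,
               level_db = lt$level_db, rating = lt$rating,
               session = paste0("S", lt$subject, "_", lt$noise_type, "_",
                                lt$level_db))
  high <- meta$rating > design$label_threshold
  sfx <- subject_effects(design, meta$subject)
  with_seed(design$seed + 1000L + idx, {
    n <- round(design$session_length_s * design$eeg_rate)
    eeg <- matrix(0, design$n_eeg_channels, n,
                  dimnames = list(EEG_CHANNELS, NULL))
    for (ch in seq_len(design$n_eeg_channels)) {
      frontal <- EEG_CHANNELS[ch] %in% FRONTAL_CHANNELS
      x <- numeric(n)
      for (b in seq_along(EEG_BANDS)) {
        spec <- EEG_BANDS[[b]]
        amp <- spec$amp * sfx$band_mult[b]
        nm <- names(EEG_BANDS)[b]
        if (high && nm == "theta" && frontal) amp <- amp * design$theta_gain
        if (high && nm == "alpha") amp <- amp * design$alpha_gain
        x <- x + amp * band_noise(n, design$eeg_rate, spec$band[1],
                                  spec$band[2])
      }
      eeg[ch, ] <- x + design$noise_sd * rnorm(n)
    }
    m <- round(design$session_length_s * design$eda_rate)
    tt <- (seq_len(m) - 1) / design$eda_rate
    tonic <- 2 * sfx$eda_mult +
      0.15 * sin(2 * pi * tt / 120 + runif(1, 0, 2 * pi)) +
      if (high) design$scl_shift else 0
    rate_min <- if (high) design$scr_rate_high else design$scr_rate_normal
    k <- rpois(1, rate_min * design$session_length_s / 60)
    phasic <- numeric(m)
    if (k > 0) {
      onsets <- sort(runif(k, 0, design$session_length_s))
      amps <- rlnorm(k, log(0.3), 0.3)
      kt <- seq(0, 12, by = 1 / design$eda_rate)
      kern <- exp(-kt / 3) - exp(-kt / 1)
      kern <- kern / max(kern)
      for (i in seq_len(k)) {
        j0 <- floor(onsets[i] * design$eda_rate) + 1
        jj <- j0:min(m, j0 + length(kern) - 1)
        phasic[jj] <- phasic[jj] + amps[i] * kern[seq_along(jj)]
      }
    }
    eda <- matrix(tonic + phasic + design$eda_noise_sd * rnorm(m), 1, m,
                  dimnames = list("EDA", NULL))
    list(eeg = new_recording(eeg, design$eeg_rate, EEG_CHANNELS, meta),
         eda = new_recording(eda, design$eda_rate, "EDA", meta))
  })
}

#' Generate a full synthetic cohort
#'
#' Generates every session of the design's label table (by default
#' 25 subjects x 6 conditions = 150 EEG/EDA session pairs). With `dir`
#' given the cohort is also written to disk (see [write_cohort()]).
#'
#' @param design a [cohort_design()].
#' @param dir optional output directory.
#' @param format on-disk signal format, `"csv"` (one column per channel) or
#'   `"rds"` (packed binary bundle); only used with `dir`.
#' @return object of class `nf_cohort`: list of sessions (each with `eeg`,
#'   `eda`), the labels data.frame, and the design.
#' @export
generate_cohort <- function(design, dir = NULL, format = c("csv", "rds")) {
  format <- match.arg(format)
  lt <- design$label_table
  sessions <- vector("list", nrow(lt))
  for (i in seq_len(nrow(lt)))
    sessions[[i]] <- generate_session(design, lt[i, ])
  labels <- data.frame(
    subject = lt$subject,
    session = vapply(sessions, function(s) s$eeg$meta$session, ""),
    noise_type = lt$noise_type, level_db = lt$level_db, rating = lt$rating
  )
  cohort <- structure(list(sessions = sessions, labels = labels,
                           design = design), class = "nf_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, format)
  cohort
}

#' @rdname generate_cohort
#' @param object,nsim,seed,... [stats::simulate()] interface: `nsim` cohorts
#'   are generated from design `object`, reseeding with `seed`, `seed + 1`,
#'   ... when `seed` is given.
#' @export
simulate.cohort_design <- function(object, nsim = 1, seed = NULL, ...) {
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    d <- object
    if (!is.null(seed)) d$seed <- seed + i - 1L
    out[[i]] <- generate_cohort(d)
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
print.nf_cohort <- function(x, ...) {
  cat(sprintf("<nf_cohort> %d sessions, %d subjects, %d high-annoyance\n",
              nrow(x$labels), length(unique(x$labels$subject)),
              sum(x$labels$rating > x$design$label_threshold)))
  invisible(x)
}

#' Write / read a cohort on disk
#'
#' `write_cohort()` stores one EEG and one EDA file per session (CSV with a
#' header of channel names, or a packed `.rds` bundle), a `labels.csv`
#' table and a JSON `manifest.json` echoing the design and seed.
#' `read_cohort()` restores the cohort from such a directory.
#'
#' @param cohort an `nf_cohort`.
#' @param dir directory (created if missing).
#' @param format `"csv"` or `"rds"`.
#' @return `write_cohort()` the directory invisibly; `read_cohort()` an
#'   `nf_cohort`.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "rds")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  for (s in cohort$sessions) {
    id <- s$eeg$meta$session
    if (format == "csv") {
      write.csv(as.data.frame(t(s$eeg$data)),
                file.path(dir, paste0("eeg_", id, ".csv")), row.names = FALSE)
      write.csv(as.data.frame(t(s$eda$data)),
                file.path(dir, paste0("eda_", id, ".csv")), row.names = FALSE)
    } else {
      saveRDS(s, file.path(dir, paste0("session_", id, ".rds")))
    }
  }
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  design <- cohort$design
  manifest <- design[setdiff(names(design), "label_table")]
  manifest$label_table <- design$label_table
  manifest$format <- format
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lt <- as.data.frame(manifest$label_table)
  args <- manifest[setdiff(names(manifest), c("label_table", "format",
                                              "sessions_per_subject"))]
  design <- do.call(cohort_design, c(args, list(label_table = lt)))
  labels <- read.csv(file.path(dir, "labels.csv"))
  sessions <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    id <- labels$session[i]
    meta <- list(subject = labels$subject[i], noise_type = labels$noise_type[i],
                 level_db = labels$level_db[i], rating = labels$rating[i],
                 session = id)
    if (identical(manifest$format, "rds")) {
      sessions[[i]] <- readRDS(file.path(dir, paste0("session_", id, ".rds")))
    } else {
      eeg <- t(as.matrix(read.csv(file.path(dir, paste0("eeg_", id, ".csv")))))
      eda <- t(as.matrix(read.csv(file.path(dir, paste0("eda_", id, ".csv")))))
      rownames(eeg) <- EEG_CHANNELS
      sessions[[i]] <- list(
        eeg = new_recording(eeg, design$eeg_rate, EEG_CHANNELS, meta),
        eda = new_recording(eda, design$eda_rate, "EDA", meta)
      )
    }
  }
  structure(list(sessions = sessions, labels = labels, design = design),
            class = "nf_cohort")
}
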