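#' Simulation configuration for a synthetic sEMG cohort
#'
#' The generator emulates band-limited stochastic EMG-like signals per
#' channel, movement-phase amplitude envelopes, and class effects localized
#' to the muscle-movement pairs most implicated in cervical spondylosis:
#' the cervical erector spinae during the bow (A1) and the upper trapezius
#' during hands-up (A7).
#'
#' @param n_cs number of CS subjects.
#' @param n_healthy number of healthy subjects.
#' @param reps repetitions (samples) per subject, default 3.
#' @param fs sampling rate in Hz, default 1000.
#' @param duration_s seconds per movement recording, default 5 (minimum 3).
#' @param effect_size nonnegative scalar scaling all class effects; 0 is the
#'   exact null (both classes drawn from one process).
#' @param missing_rate fraction of downstream feature cells to blank,
#'   in \[0, 1).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_cs, n_healthy, reps = 3L, fs = 1000,
                              duration_s = 5, effect_size = 1,
                              missing_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_cs >= 0, n_healthy >= 0, reps >= 1,
            fs > 0, duration_s >= 3, effect_size >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_cs = as.integer(n_cs), n_healthy = as.integer(n_healthy),
                 reps = as.integer(reps), fs = fs, duration_s = duration_s,
                 effect_size = effect_size, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# class-effect magnitudes at effect_size = 1; scaled as m^effect_size so
# effect_size = 0 is exactly multiplicative identity (the null)
EFFECT_DEFAULTS <- list(frr_mult = 0.55, amp_gain = 1.4, spec_compress = 0.85)

# muscle-movement pairs carrying the planted class effects
affected_pair <- function(movement, muscle) {
  (movement == "A1" && muscle %in% c("M3", "M4")) ||
    (movement == "A7" && muscle %in% c("M2", "M5"))
}

# trapezoidal rise-hold-fall profile (A2..A7)
trapezoid_envelope <- function(n, rise_frac = 0.15) {
  nr <- max(1L, round(n * rise_frac))
  env <- rep(1, n)
  env[seq_len(nr)] <- seq(0, 1, length.out = nr)
  env[(n - nr + 1L):n] <- seq(1, 0, length.out = nr)
  env
}

# three-phase motion/hold/motion profile for the bow (A1); hold_level is the
# mid-flexion suppression depth of the envelope
flexion_envelope <- function(n, hold_level) {
  b1 <- floor(n / 3); b2 <- floor(2 * n / 3)
  env <- numeric(n)
  env[1:b1] <- 1
  env[(b1 + 1):b2] <- hold_level
  env[(b2 + 1):n] <- 1
  # short smoothing to avoid step discontinuities
  k <- max(1L, round(n * 0.01))
  as.numeric(stats::filter(c(rep(env[1], k), env, rep(env[n], k)),
                           rep(1 / (2 * k + 1), 2 * k + 1),
                           sides = 2))[(k + 1):(k + n)]
}

#' Simulate one sEMG channel
#'
#' Zero-mean Gaussian noise shaped by a 4th-order Butterworth band-pass
#' (20-450 Hz, upper edge capped at 0.45*fs), amplitude-modulated by the
#' supplied envelope. For CS subjects on the affected muscle-movement pairs
#' (M3/M4 during A1, M2/M5 during A7) the amplitude is raised by
#' `1.4^effect_size` and the pass band compressed by `0.85^effect_size`
#' (a downward shift of the spectral center).
#'
#' @param movement,muscle identity, `"A1"`..`"A7"` / `"M1"`..`"M6"`.
#' @param class_label 1 = CS, 0 = healthy.
#' @param effect_size nonnegative scalar.
#' @param envelope nonnegative amplitude profile; its length sets the
#'   duration.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return a [channel_signal()].
#' @export
simulate_channel <- function(movement, muscle, class_label, effect_size,
                             envelope, fs = 1000, seed) {
  if (length(envelope) < 1 || any(envelope < 0))
    stop("envelope must be a nonnegative profile of positive length")
  n <- length(envelope)
  if (n < fs) stop("envelope shorter than 1 second at fs = ", fs)
  set.seed(seed %% .Machine$integer.max)
  affected <- class_label == 1L && affected_pair(movement, muscle)
  compress <- if (affected) EFFECT_DEFAULTS$spec_compress^effect_size else 1
  gain <- if (affected) EFFECT_DEFAULTS$amp_gain^effect_size else 1
  lo <- 20 * compress
  hi <- min(450, 0.45 * fs) * compress
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  channel_signal(0.1 * gain * envelope * x, fs, muscle, movement)
}

# per-muscle A1 hold level: erector spinae relax deeply when healthy
# (flexion-relaxation); CS loses that suppression by frr_mult^effect
a1_hold_level <- function(muscle, class_label, effect_size) {
  if (muscle %in% c("M3", "M4")) {
    base <- 0.3
    if (class_label == 1L)
      base <- min(0.95, base / EFFECT_DEFAULTS$frr_mult^effect_size)
    base
  } else 0.7
}

#' Simulate one subject sample
#'
#' Seven movements times six channels. A1 uses a motion/hold/motion envelope
#' (thirds of the recording) so the flexion-relaxation ratio is meaningful;
#' A2..A7 use trapezoidal envelopes. CS effects (reduced hold suppression of
#' M3/M4 in A1, amplitude elevation and spectral compression on the affected
#' pairs) all scale with `config$effect_size`.
#'
#' @param subject_id subject identifier.
#' @param class_label 1 = CS, 0 = healthy.
#' @param repetition repetition index 1..3.
#' @param config a [simulation_config()].
#' @param seed integer seed for this sample.
#' @return a [subject_sample()].
#' @export
simulate_subject <- function(subject_id, class_label, repetition, config,
                             seed) {
  n <- round(config$fs * config$duration_s)
  recs <- lapply(seq_along(MOVEMENTS), function(mi) {
    mov <- MOVEMENTS[mi]
    chans <- lapply(seq_along(MUSCLES), function(ci) {
      mus <- MUSCLES[ci]
      env <- if (mov == "A1") {
        flexion_envelope(n, a1_hold_level(mus, class_label,
                                          config$effect_size))
      } else {
        trapezoid_envelope(n)
      }
      simulate_channel(mov, mus, class_label, config$effect_size, env,
                       fs = config$fs, seed = seed + 97L * mi + 11L * ci)
    })
    movement_recording(mov, chans)
  })
  subject_sample(subject_id, class_label, repetition, recs)
}

#' Simulate a full cohort
#'
#' Generates `(n_cs + n_healthy) * reps` subject samples plus a reproducible
#' plan naming the feature cells to blank downstream (missing completely at
#' random over rows and canonical feature columns).
#'
#' @param config a [simulation_config()].
#' @return list with `samples` (list of [subject_sample()]) and
#'   `missing_plan` (data.frame with columns `row`, `feature`; zero rows when
#'   `missing_rate = 0`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  subjects <- c(sprintf("cs%03d", seq_len(config$n_cs)),
                sprintf("hc%03d", seq_len(config$n_healthy)))
  labels <- c(rep(1L, config$n_cs), rep(0L, config$n_healthy))
  samples <- list()
  k <- 0L
  for (si in seq_along(subjects)) {
    for (r in seq_len(config$reps)) {
      k <- k + 1L
      samples[[k]] <- simulate_subject(
        subjects[si], labels[si], r, config,
        seed = (config$seed + 7919L * si + 1009L * r) %% .Machine$integer.max)
    }
  }
  canon <- canonical_feature_names()
  n_cells <- k * length(canon)
  n_missing <- round(config$missing_rate * n_cells)
  if (n_missing > 0) {
    set.seed((config$seed + 424243L) %% .Machine$integer.max)
    cells <- sample.int(n_cells, n_missing)
    plan <- data.frame(row = ((cells - 1L) %% k) + 1L,
                       feature = canon[((cells - 1L) %/% k) + 1L],
                       stringsAsFactors = FALSE)
  } else {
    plan <- data.frame(row = integer(0), feature = character(0),
                       stringsAsFactors = FALSE)
  }
  list(samples = samples, missing_plan = plan)
}
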