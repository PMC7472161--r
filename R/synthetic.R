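#' Generate 1/f background EEG
#'
#' Independent per-channel Gaussian noise whose amplitude spectrum is
#' shaped as `1/f^(exponent/2)` (so power falls as `1/f^exponent`), scaled
#' to a target standard deviation in µV. `exponent = 0` gives a flat
#' (white) spectrum; `exponent = 1` the pink-noise-like background typical
#' of resting EEG.
#'
#' @param labels channel labels.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz).
#' @param exponent spectral exponent in `[0, 2]`.
#' @param amplitude_uv per-channel standard deviation (µV).
#' @param seed optional RNG seed (deterministic output under a fixed seed).
#' @return A [raw_recording()].
#' @export
gen_background <- function(labels, duration_s, fs, exponent = 1,
                           amplitude_uv = 20, seed = NULL) {
  if (exponent < 0 || exponent > 2) stop("exponent must be in [0, 2]")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  data <- matrix(NA_real_, length(labels), n)
  for (ch in seq_along(labels)) {
    data[ch, ] <- one_over_f_noise(n, fs, exponent, amplitude_uv)
  }
  raw_recording(data, fs, labels)
}

one_over_f_noise <- function(n, fs, exponent, amplitude_uv) {
  w <- rnorm(n)
  if (exponent == 0) return(amplitude_uv * w)
  FT <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror to physical frequency
  g <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(fft(FT * g, inverse = TRUE)) / n
  amplitude_uv * x / sd(x)
}

# Band-limited Gaussian noise (ideal DFT band selection), unit sd.
bandlimited_noise <- function(n, fs, low, high) {
  w <- rnorm(n)
  FT <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  FT[!(f >= low & f < high)] <- 0
  x <- Re(fft(FT, inverse = TRUE)) / n
  x / sd(x)
}

# Biphasic blink transient: steep positive lobe followed by a shallow
# undershoot, ~300 ms long, as seen frontally during eye blinks.
blink_waveform <- function(fs, amplitude_uv) {
  t <- seq(0, 0.3, by = 1 / fs)
  amplitude_uv * (exp(-((t - 0.08) / 0.05)^2) -
                    0.25 * exp(-((t - 0.2) / 0.07)^2))
}

add_blinks <- function(data, labels, fs, rate_per_min, seed_times = NULL) {
  frontal <- match(canonical_label(c("Fp1", "Fp2", "AF3", "AF4")), labels)
  gains <- c(1, 1, 0.6, 0.6)[!is.na(frontal)]
  frontal <- frontal[!is.na(frontal)]
  if (!length(frontal)) return(list(data = data, samples = integer(0)))
  n <- ncol(data)
  n_blinks <- stats::rpois(1, rate_per_min * n / fs / 60)
  max_start <- max(1L, n - as.integer(round(0.35 * fs)))
  starts <- sort(sample.int(max_start, min(n_blinks, max_start)))
  for (s in starts) {
    w <- blink_waveform(fs, runif(1, 100, 300))
    idx <- s:min(n, s + length(w) - 1L)
    for (j in seq_along(frontal)) {
      data[frontal[j], idx] <- data[frontal[j], idx] +
        gains[j] * w[seq_along(idx)]
    }
  }
  list(data = data, samples = starts)
}

#' Emotion-dataset simulation specification
#'
#' Defines the study conditions the emotion generator emulates: per
#' subject, `4 * n_trials_per_class` trials of `trial_s` seconds whose
#' four classes differ in the power of a band-limited oscillatory
#' component added at `signal_channels` only, on top of 1/f background,
#' with frontal eye blinks injected at Poisson times.
#'
#' @param n_subjects number of subjects (default 8).
#' @param n_trials_per_class trials per emotion class (default 10).
#' @param trial_s trial length in seconds (default 10, the desk-scale
#'   profile; the full-scale analogue is 60).
#' @param fs sampling rate (default 128; full scale 512).
#' @param signal_channels channels carrying the class-dependent signal.
#' @param target_band band (Hz) of the class signal (default alpha 8-13).
#' @param effect named per-class amplitude multipliers of the class signal.
#' @param signal_uv base class-signal standard deviation (µV).
#' @param noise_exponent,noise_uv background 1/f exponent and sd.
#' @param blink_rate blinks per minute.
#' @param rng_seed base seed (subject i uses `rng_seed + i`).
#' @return A list of class `emotion_sim_spec`.
#' @export
emotion_sim_spec <- function(n_subjects = 8, n_trials_per_class = 10,
                             trial_s = 10, fs = 128,
                             signal_channels = c("F7", "F8"),
                             target_band = c(8, 13),
                             effect = c(HAHV = 0.2, HALV = 1,
                                        LAHV = 2.2, LALV = 3.5),
                             signal_uv = 10, noise_exponent = 1,
                             noise_uv = 20, blink_rate = 10,
                             rng_seed = 1) {
  if (length(effect) != 4) stop("four emotion classes required")
  if (any(effect <= 0)) stop("effect multipliers must be positive")
  structure(as.list(environment()), class = "emotion_sim_spec")
}

#' Generate a synthetic emotion dataset
#'
#' @param spec an [emotion_sim_spec()].
#' @param montage the montage providing channel labels.
#' @return List of per-subject lists with elements `recording` (a
#'   [raw_recording()] with trial bounds and labels), `trial_labels`,
#'   and `blink_samples` (ground-truth blink onset samples).
#' @export
gen_emotion_dataset <- function(spec = emotion_sim_spec(),
                                montage = default_montage()) {
  labels <- montage$all_channels
  classes <- names(spec$effect)
  n_trials <- 4L * spec$n_trials_per_class
  len <- round(spec$trial_s * spec$fs)
  sig_idx <- match(canonical_label(spec$signal_channels), labels)
  if (anyNA(sig_idx)) stop("signal channel not in montage")
  lapply(seq_len(spec$n_subjects), function(si) {
    set.seed(spec$rng_seed + si)
    y <- sample(rep(classes, each = spec$n_trials_per_class))
    data <- matrix(NA_real_, length(labels), n_trials * len)
    for (ch in seq_along(labels)) {
      data[ch, ] <- one_over_f_noise(n_trials * len, spec$fs,
                                     spec$noise_exponent, spec$noise_uv)
    }
    bounds <- cbind((seq_len(n_trials) - 1L) * len + 1L,
                    seq_len(n_trials) * len)
    for (tr in seq_len(n_trials)) {
      amp <- spec$signal_uv * spec$effect[y[tr]] * runif(1, 0.9, 1.1)
      for (ch in sig_idx) {
        data[ch, bounds[tr, 1]:bounds[tr, 2]] <-
          data[ch, bounds[tr, 1]:bounds[tr, 2]] +
          amp * bandlimited_noise(len, spec$fs, spec$target_band[1],
                                  spec$target_band[2])
      }
    }
    bl <- add_blinks(data, labels, spec$fs, spec$blink_rate)
    list(recording = raw_recording(bl$data, spec$fs, labels,
                                   trial_bounds = bounds,
                                   trial_labels = y),
         trial_labels = y, blink_samples = bl$samples)
  })
}

#' Attention-dataset simulation specification
#'
#' Defines the study conditions the attention generator emulates: a long
#' stream of short d2-style trials; a slowly drifting latent attention
#' process in `[0, 1]` (smoothed random walk) drives both the per-trial
#' probability of a correct response (`P(correct) = accuracy_floor +
#' accuracy_gain * drift`) and the amplitude of a band-limited component
#' at the coupling channels, so behavioral CONC and EEG band power
#' co-vary.
#'
#' @param n_subjects number of subjects (default 8).
#' @param n_trials trials per subject (default 400, the desk-scale
#'   profile; the full-scale analogue is 1316).
#' @param trial_s trial length in seconds (default 1).
#' @param fs sampling rate (default 128).
#' @param target_frac fraction of target trials in (0, 1).
#' @param coupling_channels channels whose band power tracks the drift.
#' @param coupling_band band (Hz) of the coupled component.
#' @param coupling_strength scales the drift-to-amplitude slope; 0
#'   decouples EEG from behavior entirely.
#' @param coupling_dominance relative weight of the non-dominant coupling
#'   channels: each subject couples most strongly at one of the coupling
#'   channels (rotating across subjects), the others at this fraction,
#'   emulating inter-individual variability in where the attention
#'   signature is strongest.
#' @param signal_uv base coupled-signal standard deviation (µV).
#' @param accuracy_floor,accuracy_gain the monotone drift-to-accuracy map.
#' @param drift_smooth moving-average width (trials) of the random walk.
#' @param noise_exponent,noise_uv background 1/f exponent and sd.
#' @param blink_rate blinks per minute.
#' @param rng_seed base seed (subject i uses `rng_seed + i`).
#' @return A list of class `attention_sim_spec`.
#' @export
attention_sim_spec <- function(n_subjects = 8, n_trials = 400,
                               trial_s = 1, fs = 128, target_frac = 0.5,
                               coupling_channels = c("Fz", "Pz"),
                               coupling_band = c(8, 13),
                               coupling_strength = 1,
                               coupling_dominance = 0, signal_uv = 20,
                               accuracy_floor = 0.25,
                               accuracy_gain = 0.7,
                               drift_smooth = 51, noise_exponent = 1,
                               noise_uv = 20, blink_rate = 2,
                               rng_seed = 1) {
  if (target_frac <= 0 || target_frac >= 1) {
    stop("target_frac must be in (0, 1)")
  }
  if (accuracy_floor + accuracy_gain > 1 || accuracy_floor < 0) {
    stop("accuracy link must map [0,1] into [0,1]")
  }
  structure(as.list(environment()), class = "attention_sim_spec")
}

# Smoothed random walk rescaled to [0, 1].
latent_drift <- function(n, smooth) {
  rw <- cumsum(rnorm(n))
  k <- min(smooth, n)
  pad <- c(rep(rw[1], k), rw, rep(rw[n], k))
  sm <- stats::filter(pad, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)[k + seq_len(n)]
  rng <- range(sm)
  if (rng[1] == rng[2]) return(rep(0.5, n))
  (sm - rng[1]) / (rng[2] - rng[1])
}

#' Generate a synthetic attention dataset
#'
#' @param spec an [attention_sim_spec()].
#' @param montage the montage providing channel labels.
#' @return List of per-subject lists with elements `recording` (trial
#'   bounds aligned to the stream), `stream` (a [behavioral_stream()]),
#'   `drift` (the ground-truth latent attention series) and
#'   `blink_samples`.
#' @export
gen_attention_dataset <- function(spec = attention_sim_spec(),
                                  montage = default_montage()) {
  labels <- montage$all_channels
  len <- round(spec$trial_s * spec$fs)
  cpl_idx <- match(canonical_label(spec$coupling_channels), labels)
  if (anyNA(cpl_idx)) stop("coupling channel not in montage")
  lapply(seq_len(spec$n_subjects), function(si) {
    set.seed(spec$rng_seed + si)
    drift <- latent_drift(spec$n_trials, spec$drift_smooth)
    is_target <- runif(spec$n_trials) < spec$target_frac
    p_correct <- spec$accuracy_floor + spec$accuracy_gain * drift
    correct <- runif(spec$n_trials) < p_correct
    data <- matrix(NA_real_, length(labels), spec$n_trials * len)
    for (ch in seq_along(labels)) {
      data[ch, ] <- one_over_f_noise(spec$n_trials * len, spec$fs,
                                     spec$noise_exponent, spec$noise_uv)
    }
    bounds <- cbind((seq_len(spec$n_trials) - 1L) * len + 1L,
                    seq_len(spec$n_trials) * len)
    dominant <- ((si - 1L) %% length(cpl_idx)) + 1L
    weights <- rep(spec$coupling_dominance, length(cpl_idx))
    weights[dominant] <- 1
    for (tr in seq_len(spec$n_trials)) {
      amp <- spec$signal_uv *
        (0.2 + spec$coupling_strength * drift[tr])
      for (j in seq_along(cpl_idx)) {
        data[cpl_idx[j], bounds[tr, 1]:bounds[tr, 2]] <-
          data[cpl_idx[j], bounds[tr, 1]:bounds[tr, 2]] +
          weights[j] * amp * bandlimited_noise(len, spec$fs,
                                               spec$coupling_band[1],
                                               spec$coupling_band[2])
      }
    }
    bl <- add_blinks(data, labels, spec$fs, spec$blink_rate)
    list(recording = raw_recording(bl$data, spec$fs, labels,
                                   trial_bounds = bounds),
         stream = behavioral_stream(is_target, correct),
         drift = drift, blink_samples = bl$samples)
  })
}
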