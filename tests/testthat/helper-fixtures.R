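# Shared fixtures built in code.

# A small symmetric montage (2 pairs + 2 midline, 6 channels) that keeps
# exhaustive searches tiny in tests.
small_montage <- function() {
  montage(midline = c("Fz", "Pz"),
          pairs = list(c("F7", "F8"), c("O1", "O2")))
}

# Brute-force enumeration oracle: filter all k-subsets of the montage's
# channels by the symmetry predicate (each pair fully in or out).
brute_force_symmetric <- function(montage, k) {
  ch <- montage$all_channels
  combos <- combn(length(ch), k)
  pair_id <- integer(length(ch))
  for (r in seq_len(nrow(montage$pairs))) {
    pair_id[match(montage$pairs[r, ], ch)] <- r
  }
  ids <- matrix(pair_id[combos], nrow = k)
  ok <- rep(TRUE, ncol(combos))
  for (r in seq_len(nrow(montage$pairs))) {
    ok <- ok & colSums(ids == r) != 1   # a pair is in with 0 or 2 members
  }
  apply(combos[, ok, drop = FALSE], 2,
        function(idx) paste(sort(ch[idx]), collapse = "+"))
}

# A deterministic multi-channel recording of sinusoids plus noise.
toy_recording <- function(n_ch = 4, fs = 128, dur_s = 4, seed = 42) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  data <- t(sapply(seq_len(n_ch), function(i)
    sin(2 * pi * (5 + i) * t) + 0.1 * rnorm(length(t))))
  raw_recording(data, fs, paste0("C", seq_len(n_ch) * 2 - 1)[seq_len(n_ch)],
                trial_bounds = NULL)
}

# Minimal labeled-features context for cv_accuracy: random features plus
# random (well-conditioned) band covariances for the CSP refits.
make_lf <- function(n_epochs, n_feat, y, trial = seq_along(y),
                    n_ch = 2, bands = eeg_bands()[1, , drop = FALSE],
                    seed = 1) {
  set.seed(seed)
  covs <- array(NA_real_, c(n_epochs, nrow(bands), n_ch, n_ch))
  for (i in seq_len(n_epochs)) {
    for (b in seq_len(nrow(bands))) {
      A <- matrix(rnorm(n_ch * n_ch), n_ch)
      covs[i, b, , ] <- crossprod(A) + diag(n_ch)
    }
  }
  dimnames(covs) <- list(NULL, bands$name, paste0("ch", seq_len(n_ch)),
                         paste0("ch", seq_len(n_ch)))
  list(values = matrix(rnorm(n_epochs * n_feat), n_epochs,
                       dimnames = list(NULL, paste0("f", seq_len(n_feat)))),
       desc = NULL, covs = covs, y = y, trial = trial, bands = bands)
}

# Small emotion dataset prepared end to end on the small montage.
small_emotion_subjects <- function(n_subjects = 2, seed = 11,
                                   trial_s = 3, n_per_class = 3) {
  m <- small_montage()
  spec <- emotion_sim_spec(n_subjects = n_subjects,
                           n_trials_per_class = n_per_class,
                           trial_s = trial_s, fs = 128, blink_rate = 0,
                           rng_seed = seed)
  ds <- gen_emotion_dataset(spec, m)
  lapply(seq_along(ds), function(i) {
    er <- preprocess_recording(ds[[i]]$recording, detector = NULL)
    prepare_emotion_subject(er, paste0("s", i), m)
  })
}

# Small attention dataset prepared end to end on the small montage.
small_attention_subjects <- function(n_subjects = 2, seed = 11,
                                     n_trials = 150, win = 30,
                                     coupling = c("Fz", "Pz"), ...) {
  m <- small_montage()
  spec <- attention_sim_spec(n_subjects = n_subjects, n_trials = n_trials,
                             coupling_channels = coupling,
                             blink_rate = 0, rng_seed = seed, ...)
  ds <- gen_attention_dataset(spec, m)
  lapply(seq_along(ds), function(i) {
    suppressWarnings(prepare_attention_subject(
      ds[[i]]$recording, ds[[i]]$stream, paste0("s", i),
      window_spec(win, 0.5), m, detector = NULL))
  })
}
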