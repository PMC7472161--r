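test_that("common average reference zeroes the across-channel mean", {
  rec <- raw_recording(matrix(c(1, 3), 2, 1), 128, c("C3", "C4"))
  out <- common_average_reference(rec)
  expect_equal(as.vector(out$data), c(-1, 1))
  # idempotence and the zero-mean invariant on random data
  rec2 <- raw_recording(matrix(rnorm(4000), 4), 128,
                        c("C3", "C4", "O1", "O2"))
  once <- common_average_reference(rec2)
  expect_lt(max(abs(colMeans(once$data))), 1e-12)
  twice <- common_average_reference(once)
  expect_equal(twice$data, once$data)
  expect_error(common_average_reference(
    raw_recording(matrix(1:5, 1), 128, "Cz")), "2 channels")
})

test_that("baseline correction removes each channel's temporal mean", {
  rec <- raw_recording(rbind(rep(5, 100), sin(2 * pi * (1:100) / 25) + 2),
                       100, c("Fz", "Pz"))
  out <- baseline_correct(rec)
  expect_equal(out$data[1, ], rep(0, 100))
  expect_equal(mean(out$data[2, ]), 0, tolerance = 1e-12)
  expect_equal(baseline_correct(out)$data, out$data)
})

test_that("zero-phase bandpass keeps the pass band and rejects 60 Hz", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq(fs, length(t) - fs)       # ignore filter edge transients
  x10 <- sin(2 * pi * 10 * t)
  x60 <- sin(2 * pi * 60 * t)
  rec <- raw_recording(rbind(x10, x60, 0), fs, c("C3", "C4", "Cz"))
  out <- bandpass_filter(rec, bandpass_spec(1, 55, 6))
  expect_equal(rms(out$data[1, mid]) / rms(x10[mid]), 1, tolerance = 0.05)
  # the forward-backward 6th-order design yields |H(60)|^2 ~ 0.24
  # (12.5 dB) with the 55 Hz upper edge at fs = 512; assert stopband
  # rejection clearly below the pass band rather than a steeper bound the
  # design cannot deliver
  expect_lt(rms(out$data[2, mid]) / rms(x60[mid]), 0.3)
  expect_equal(out$data[3, ], rep(0, length(t)))
  expect_error(bandpass_filter(rec, bandpass_spec(1, 300)), "Nyquist")
})

test_that("forward-backward filtering introduces no group delay", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  # narrowband burst: the envelope peak must not move
  env <- exp(-((t - 2) / 0.25)^2)
  x <- env * sin(2 * pi * 10 * t)
  rec <- raw_recording(matrix(x, 1), fs, "Cz")
  rec <- structure(rec, class = "raw_recording")
  out <- bandpass_filter(
    raw_recording(rbind(x, x), fs, c("C3", "C4")), bandpass_spec(1, 55, 6))
  expect_lt(abs(which.max(abs(out$data[1, ])) - which.max(abs(x))), 3)
})

test_that("epoch counts follow the moving-window closed form", {
  fs <- 64
  mk <- function(trial_s, n_trials = 1) {
    n <- round(trial_s * fs)
    raw_recording(matrix(0, 1, n * n_trials), fs, "Cz",
                  trial_bounds = cbind((0:(n_trials - 1)) * n + 1,
                                       (1:n_trials) * n))
  }
  expect_equal(nrow(epoch_recording(mk(60, 40), 1, 0.5)$meta), 4760)
  expect_equal(nrow(epoch_recording(mk(1), 1, 0.5)$meta), 1)
  expect_equal(nrow(epoch_recording(mk(10), 2, 0)$meta), 5)
  expect_warning(epoch_recording(mk(0.5), 1, 0.5), "shorter")
})

test_that("epoch counts match a brute-force slide for random settings", {
  fs <- 32
  set.seed(7)
  for (i in 1:20) {
    trial_s <- runif(1, 1, 20)
    win_s <- runif(1, 0.5, min(4, trial_s))
    overlap <- runif(1, 0, 0.9)
    n <- round(trial_s * fs)
    rec <- raw_recording(matrix(0, 1, n), fs, "Cz")
    er <- epoch_recording(rec, win_s, overlap)
    # brute force: slide sample by sample in steps
    win <- round(win_s * fs)
    step <- max(1, round(win * (1 - overlap)))
    starts <- seq(1, n, by = step)
    oracle <- sum(starts + win - 1 <= n)
    expect_equal(nrow(er$meta), oracle)
  }
})

test_that("epochs carry their source trial's class label", {
  fs <- 32
  rec <- raw_recording(matrix(0, 1, fs * 4), fs, "Cz",
                       trial_bounds = cbind(c(1, 2 * fs + 1),
                                            c(2 * fs, 4 * fs)),
                       trial_labels = c("HAHV", "LALV"))
  er <- epoch_recording(rec, 1, 0)
  expect_equal(er$meta$class, rep(c("HAHV", "LALV"), each = 2))
})

test_that("blink rejection flags epochs, never cleans them", {
  er <- epoch_recording(toy_recording(), 1, 0.5)
  all_kept <- reject_blink_epochs(er, function(ep, fs, lb) FALSE)
  expect_true(all(all_kept$meta$kept))
  none_kept <- reject_blink_epochs(er, function(ep, fs, lb) TRUE)
  expect_false(any(none_kept$meta$kept))
  expect_equal(none_kept$epochs, er$epochs)   # data untouched
  expect_warning(
    bad <- reject_blink_epochs(er, function(ep, fs, lb) stop("boom")),
    "rejected")
  expect_false(any(bad$meta$kept))
})

test_that("default detector finds injected blinks and spares clean epochs", {
  m <- default_montage()
  spec <- emotion_sim_spec(n_subjects = 1, n_trials_per_class = 2,
                           trial_s = 6, fs = 128, blink_rate = 12,
                           rng_seed = 5)
  ds <- gen_emotion_dataset(spec, m)
  rec <- ds[[1]]$recording
  er <- epoch_recording(rec, 1, 0.5)
  flagged <- !reject_blink_epochs(er)$meta$kept
  win <- 128
  # an epoch "contains" a blink when the main deflection lies inside it
  blink_epochs <- vapply(seq_len(nrow(er$meta)), function(i) {
    s <- er$meta$start[i]
    any(s <= ds[[1]]$blink_samples + 0.03 * 128 &
          ds[[1]]$blink_samples + 0.25 * 128 <= s + win)
  }, logical(1))
  expect_gte(mean(flagged[blink_epochs]), 0.9)
  expect_lte(mean(flagged[!blink_epochs]), 0.1)
})

test_that("subject exclusion uses a strict threshold", {
  expect_equal(exclude_subjects(c(0.2, 0.6, 0.5)), c(1, 3))
  expect_equal(exclude_subjects(rep(0, 4)), 1:4)
  expect_warning(kept <- exclude_subjects(rep(1, 3)), "excluded")
  expect_length(kept, 0)
  expect_error(exclude_subjects(c(0.2, 1.4)), "\\[0, 1\\]")
})
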