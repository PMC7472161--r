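#' Raw multichannel EEG recording
#'
#' A channels x samples matrix in microvolts with a sampling rate, channel
#' labels, and optional per-trial sample bounds and trial labels.
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param fs sampling rate in Hz.
#' @param labels channel labels, one per row of `data`.
#' @param trial_bounds optional two-column matrix of (start, end) sample
#'   indices (inclusive, 1-based) per trial; non-overlapping, in order.
#' @param trial_labels optional per-trial class labels (factor or character).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, labels, trial_bounds = NULL,
                          trial_labels = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop("fs must be positive")
  labels <- canonical_label(labels)
  if (length(labels) != nrow(data)) {
    stop("labels length (", length(labels), ") must equal channel count (",
         nrow(data), ")")
  }
  if (!is.null(trial_bounds)) {
    trial_bounds <- as.matrix(trial_bounds)
    if (ncol(trial_bounds) != 2) stop("trial_bounds needs 2 columns")
    if (any(trial_bounds < 1) || any(trial_bounds > ncol(data))) {
      stop("trial bounds outside the recording")
    }
    if (any(trial_bounds[, 2] < trial_bounds[, 1])) {
      stop("trial end before start")
    }
    if (nrow(trial_bounds) > 1 &&
        any(trial_bounds[-1, 1] <= trial_bounds[-nrow(trial_bounds), 2])) {
      stop("trial bounds overlap or are out of order")
    }
    if (!is.null(trial_labels) && length(trial_labels) != nrow(trial_bounds)) {
      stop("one trial label per trial required")
    }
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 trial_bounds = trial_bounds, trial_labels = trial_labels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$fs, " Hz",
      if (!is.null(x$trial_bounds)) paste0(", ", nrow(x$trial_bounds),
                                           " trials"), "\n", sep = "")
  invisible(x)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels, so the output's
#' across-channel mean is zero everywhere. Idempotent.
#'
#' @param rec a [raw_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  if (nrow(rec$data) < 2) {
    stop("common average reference needs at least 2 channels")
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Baseline correction
#'
#' Subtracts each channel's temporal mean so every channel is zero-mean.
#' Idempotent.
#'
#' @param rec a [raw_recording()].
#' @return The baseline-corrected recording.
#' @export
baseline_correct <- function(rec) {
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Bandpass specification
#'
#' @param low_hz,high_hz cutoff frequencies (Hz), `0 < low < high`.
#' @param order Butterworth design order (the zero-phase forward-backward
#'   pass doubles the effective magnitude order).
#' @param zero_phase apply forward and backward (no group delay)?
#' @return A list of class `bandpass_spec`. Defaults: 1-55 Hz, order 6,
#'   zero phase.
#' @export
bandpass_spec <- function(low_hz = 1, high_hz = 55, order = 6,
                          zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low < high")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "bandpass_spec")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters each channel with a Butterworth IIR bandpass. With
#' `zero_phase = TRUE` the filter runs forward and backward
#' ([signal::filtfilt()]), giving zero group delay and squared magnitude
#' response.
#'
#' @param rec a [raw_recording()].
#' @param spec a [bandpass_spec()]; cutoffs must be below Nyquist.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, spec = bandpass_spec()) {
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq) {
    stop("high cutoff ", spec$high_hz, " Hz is at or above Nyquist (",
         nyq, " Hz)")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  f <- if (spec$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  rec$data <- t(apply(rec$data, 1, f))
  rec
}

#' Segment a recording into overlapping epochs
#'
#' Epochs are cut within each trial (or the whole recording when no trial
#' bounds are set) using a moving window: for a trial of T seconds the
#' number of epochs is `floor((T - win_s) / (win_s * (1 - overlap))) + 1`.
#' Sample intervals are half-open `[start, start + win_s * fs)`; the step is
#' `round(win_s * fs * (1 - overlap))` samples. The defaults (1 s window,
#' 50% overlap) give 119 epochs per 60-s trial.
#'
#' @param rec a [raw_recording()].
#' @param win_s window length in seconds (`win_s * fs >= 2`).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return An `epoched_recording`: `epochs` array (epochs x channels x
#'   samples), `fs`, `labels`, and `meta` data frame with per-epoch `trial`,
#'   `class` and `kept` columns.
#' @export
epoch_recording <- function(rec, win_s = 1, overlap = 0.5) {
  win <- round(win_s * rec$fs)
  if (win < 2) stop("window must span at least 2 samples")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(win * (1 - overlap))))
  bounds <- rec$trial_bounds
  if (is.null(bounds)) bounds <- matrix(c(1L, ncol(rec$data)), 1)
  starts <- integer(0); trial_of <- integer(0)
  for (tr in seq_len(nrow(bounds))) {
    len <- bounds[tr, 2] - bounds[tr, 1] + 1L
    if (len < win) {
      warning("trial ", tr, " shorter than the window; no epochs produced")
      next
    }
    n_ep <- (len - win) %/% step + 1L
    s <- bounds[tr, 1] + step * (seq_len(n_ep) - 1L)
    starts <- c(starts, s)
    trial_of <- c(trial_of, rep(tr, n_ep))
  }
  n_ch <- nrow(rec$data)
  ep <- array(NA_real_, c(length(starts), n_ch, win))
  for (i in seq_along(starts)) {
    ep[i, , ] <- rec$data[, starts[i]:(starts[i] + win - 1L)]
  }
  cls <- if (!is.null(rec$trial_labels)) {
    as.character(rec$trial_labels)[trial_of]
  } else rep(NA_character_, length(starts))
  structure(list(
    epochs = ep, fs = rec$fs, labels = rec$labels,
    meta = data.frame(trial = trial_of, class = cls,
                      kept = rep(TRUE, length(starts)),
                      start = starts)),
    class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat("<epoched_recording> ", dim(x$epochs)[1], " epochs x ",
      dim(x$epochs)[2], " ch x ", dim(x$epochs)[3], " samples @ ",
      x$fs, " Hz (", sum(x$meta$kept), " kept)\n", sep = "")
  invisible(x)
}

#' Default eye-blink detector
#'
#' Returns a detector closure for [reject_blink_epochs()]. An epoch is
#' flagged when, on the monitored frontal channels (Fp1, Fp2, AF3, AF4 when
#' present, otherwise all channels), the peak-to-peak amplitude within any
#' 200-ms sub-window exceeds `threshold_uv` and the excursion has the
#' blink-typical shape: a steep positive deflection followed by the return
#' (the maximum positive derivative precedes the maximum negative
#' derivative inside the sub-window).
#'
#' @param threshold_uv peak-to-peak threshold in µV (default 100).
#' @param frontal channels to monitor when present.
#' @param subwin_s sub-window length in seconds (default 0.2).
#' @return A function `(epoch_matrix, fs, labels) -> logical(1)`.
#' @export
default_blink_detector <- function(threshold_uv = 100,
                                   frontal = c("Fp1", "Fp2", "AF3", "AF4"),
                                   subwin_s = 0.2) {
  frontal <- canonical_label(frontal)
  function(epoch, fs, labels) {
    mon <- which(labels %in% frontal)
    if (!length(mon)) mon <- seq_along(labels)
    w <- max(2L, round(subwin_s * fs))
    n <- ncol(epoch)
    for (ch in mon) {
      x <- epoch[ch, ]
      starts <- seq(1L, max(1L, n - w + 1L), by = max(1L, w %/% 2L))
      for (s in starts) {
        seg <- x[s:min(n, s + w - 1L)]
        if (max(seg) - min(seg) > threshold_uv) {
          d <- diff(seg)
          if (which.max(d) <= which.min(d)) return(TRUE)
        }
      }
    }
    FALSE
  }
}

#' Reject epochs containing eye blinks
#'
#' Clears the `kept` flag of every epoch the detector flags; nothing is
#' interpolated or cleaned (rejection, not correction). A detector that
#' errors on an epoch counts as a flag (the epoch is rejected).
#'
#' @param er an `epoched_recording`.
#' @param detector a function `(epoch_matrix, fs, labels) -> logical(1)`,
#'   e.g. [default_blink_detector()].
#' @return The recording with updated `kept` flags and an attribute
#'   `rejection_ratio` (fraction of epochs rejected by this pass).
#' @export
reject_blink_epochs <- function(er, detector = default_blink_detector()) {
  n <- dim(er$epochs)[1]
  flagged <- logical(n)
  for (i in seq_len(n)) {
    flagged[i] <- tryCatch(
      isTRUE(detector(er$epochs[i, , , drop = TRUE], er$fs, er$labels)),
      error = function(e) {
        warning("detector failed on epoch ", i, " (", conditionMessage(e),
                "); epoch rejected")
        TRUE
      })
  }
  er$meta$kept <- er$meta$kept & !flagged
  attr(er, "rejection_ratio") <- mean(flagged)
  er
}

#' Exclude subjects by epoch-rejection ratio
#'
#' Subjects whose fraction of rejected epochs exceeds the threshold are
#' dropped (strictly greater: a ratio exactly at the threshold is kept).
#'
#' @param rejection_ratios named or unnamed numeric vector of per-subject
#'   rejection fractions in `[0, 1]`.
#' @param threshold exclusion threshold (default 0.5).
#' @return Integer indices of the kept subjects, in input order.
#' @export
exclude_subjects <- function(rejection_ratios, threshold = 0.5) {
  if (any(rejection_ratios < 0 | rejection_ratios > 1)) {
    stop("rejection ratios must lie in [0, 1]")
  }
  keep <- which(rejection_ratios <= threshold)
  if (!length(keep)) warning("all subjects excluded")
  keep
}

#' Full preprocessing chain
#'
#' Common average reference, baseline correction, zero-phase bandpass,
#' epoching, and blink-epoch rejection, in that order.
#'
#' @param rec a [raw_recording()].
#' @param band a [bandpass_spec()].
#' @param win_s,overlap epoching parameters (see [epoch_recording()]).
#' @param detector blink detector, or `NULL` to skip rejection.
#' @return An `epoched_recording`.
#' @export
preprocess_recording <- function(rec, band = bandpass_spec(), win_s = 1,
                                 overlap = 0.5,
                                 detector = default_blink_detector()) {
  rec <- common_average_reference(rec)
  rec <- baseline_correct(rec)
  rec <- bandpass_filter(rec, band)
  er <- epoch_recording(rec, win_s = win_s, overlap = overlap)
  if (!is.null(detector)) er <- reject_blink_epochs(er, detector)
  er
}
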