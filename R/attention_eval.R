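#' Normalized concentration performance
#'
#' `CONC = (NCT - NIT) / NTT` where NCT is the number of correctly
#' discriminated targets, NIT the number of incorrectly discriminated
#' targets, and NTT the total number of targets in the window. Range
#' `[-1, 1]`.
#'
#' @param nct,nit,ntt target counts, `ntt >= 1`, `nct + nit <= ntt`.
#' @return CONC value.
#' @export
conc <- function(nct, nit, ntt) {
  if (any(ntt < 1)) stop("window contains no targets (NTT = 0)")
  if (any(nct + nit > ntt)) stop("NCT + NIT exceeds NTT")
  (nct - nit) / ntt
}

#' Behavioral trial stream
#'
#' Per-trial flags from a sustained-attention (d2-style) task: whether the
#' trial presented a target and whether the response was correct.
#'
#' @param is_target logical per trial.
#' @param correct logical per trial.
#' @return A data frame of class `behavioral_stream` with columns
#'   `trial_index`, `is_target`, `correct`.
#' @export
behavioral_stream <- function(is_target, correct) {
  if (length(is_target) != length(correct)) {
    stop("is_target and correct must have equal length")
  }
  structure(data.frame(trial_index = seq_along(is_target),
                       is_target = as.logical(is_target),
                       correct = as.logical(correct)),
            class = c("behavioral_stream", "data.frame"))
}

#' Sliding-window specification over trials
#'
#' @param win_trials window length in trials (default 94).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5); the step is
#'   `round(win_trials * (1 - overlap))` trials.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(win_trials = 94, overlap = 0.5) {
  if (win_trials < 1) stop("win_trials must be >= 1")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(win_trials = win_trials, overlap = overlap,
                 step = max(1L, as.integer(round(win_trials *
                                                   (1 - overlap))))),
            class = "window_spec")
}

#' Sliding trial windows
#'
#' Number of windows is `floor((n_trials - win) / step) + 1`; with the
#' defaults (94-trial window, 50% overlap) a 1316-trial stream yields 27
#' windows.
#'
#' @param stream a [behavioral_stream()] or a trial count.
#' @param spec a [window_spec()].
#' @return Two-column matrix of inclusive (start, end) trial indices.
#' @export
sliding_windows <- function(stream, spec = window_spec()) {
  n <- if (is.numeric(stream)) stream else nrow(stream)
  if (n < spec$win_trials) {
    stop("stream has ", n, " trials, fewer than the ", spec$win_trials,
         "-trial window")
  }
  n_w <- (n - spec$win_trials) %/% spec$step + 1L
  starts <- 1L + spec$step * (seq_len(n_w) - 1L)
  cbind(start = starts, end = starts + spec$win_trials - 1L)
}

#' Per-window CONC values
#'
#' Counts NCT/NIT/NTT over the kept target trials of each window and
#' applies [conc()]. A window whose kept trials contain no target gets
#' `NA` (dropped pairwise from downstream correlations) with a warning.
#'
#' @param stream a [behavioral_stream()].
#' @param windows matrix from [sliding_windows()].
#' @param kept logical per trial (blink-rejection mask); default all kept.
#' @return Numeric CONC per window (`NA` where undefined).
#' @export
window_conc <- function(stream, windows, kept = NULL) {
  if (is.null(kept)) kept <- rep(TRUE, nrow(stream))
  out <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    idx <- windows[w, 1]:windows[w, 2]
    idx <- idx[kept[idx]]
    tgt <- stream$is_target[idx]
    ntt <- sum(tgt)
    if (ntt == 0) next
    nct <- sum(tgt & stream$correct[idx])
    out[w] <- conc(nct, ntt - nct, ntt)
  }
  if (all(is.na(out))) stop("no usable windows (all windows lack targets)")
  if (anyNA(out)) warning(sum(is.na(out)), " window(s) without targets")
  out
}

#' Prepare a subject's attention data for configuration evaluation
#'
#' Preprocesses the recording (common average reference, baseline,
#' zero-phase bandpass), cuts it into trial-level epochs, rejects
#' blink-contaminated trials, computes the CONC series over sliding trial
#' windows, and caches per-window per-channel features and band-limited
#' covariances for all montage channels (each window's features are
#' computed on the concatenation of its kept trials). Evaluating a channel
#' set afterwards is a cheap slice of this cache.
#'
#' @param rec a [raw_recording()] with per-trial bounds aligned to the
#'   behavioral stream.
#' @param stream a [behavioral_stream()] with one row per trial.
#' @param subject_id identifier used in reports.
#' @param wspec a [window_spec()].
#' @param montage the montage.
#' @param bands band definitions.
#' @param band bandpass specification.
#' @param detector blink detector applied per trial (`NULL` disables).
#' @param n_bins,hoc_lags battery parameters.
#' @return An object of class `attention_subject`.
#' @export
prepare_attention_subject <- function(rec, stream, subject_id = "s1",
                                      wspec = window_spec(),
                                      montage = default_montage(),
                                      bands = eeg_bands(),
                                      band = bandpass_spec(),
                                      detector = default_blink_detector(),
                                      n_bins = 16, hoc_lags = c(1, 2)) {
  if (is.null(rec$trial_bounds) || nrow(rec$trial_bounds) != nrow(stream)) {
    stop("recording must carry one trial per behavioral-stream row")
  }
  rec <- common_average_reference(rec)
  rec <- baseline_correct(rec)
  rec <- bandpass_filter(rec, band)
  n_trials <- nrow(rec$trial_bounds)
  kept <- rep(TRUE, n_trials)
  if (!is.null(detector)) {
    for (tr in seq_len(n_trials)) {
      seg <- rec$data[, rec$trial_bounds[tr, 1]:rec$trial_bounds[tr, 2],
                      drop = FALSE]
      kept[tr] <- !tryCatch(isTRUE(detector(seg, rec$fs, rec$labels)),
                            error = function(e) TRUE)
    }
  }
  windows <- sliding_windows(stream, wspec)
  conc_series <- window_conc(stream, windows, kept)
  ch <- intersect(montage$all_channels, rec$labels)
  ch_idx <- match(ch, rec$labels)
  n_w <- nrow(windows)
  chvals <- NULL
  covs <- array(NA_real_, c(n_w, nrow(bands), length(ch), length(ch)))
  masks_cache <- list()
  for (w in seq_len(n_w)) {
    idx <- windows[w, 1]:windows[w, 2]
    idx <- idx[kept[idx]]
    if (!length(idx)) next
    cols <- unlist(lapply(idx, function(tr)
      rec$trial_bounds[tr, 1]:rec$trial_bounds[tr, 2]))
    X <- t(rec$data[ch_idx, cols, drop = FALSE])   # samples x channels
    blk <- channel_feature_block(X, rec$fs, bands, n_bins, hoc_lags,
                                 kc_max_samples = 2048)
    if (is.null(chvals)) {
      chvals <- matrix(NA_real_, n_w, length(ch) * nrow(blk))
    }
    chvals[w, ] <- as.vector(blk)                  # feature-major per ch
    n <- nrow(X)
    key <- as.character(n)
    if (is.null(masks_cache[[key]])) {
      masks_cache[[key]] <- lapply(seq_len(nrow(bands)), function(b) {
        pos <- band_bins(n, rec$fs, bands$low[b], bands$high[b])
        mir <- n + 2L - pos
        c(pos, mir[mir > floor(n / 2) + 1 & mir <= n])
      })
    }
    FT <- stats::mvfft(X)
    for (b in seq_len(nrow(bands))) {
      Fb <- FT[masks_cache[[key]][[b]], , drop = FALSE]
      covs[w, b, , ] <- Re(crossprod(Conj(Fb), Fb)) / (n * n)
    }
  }
  fam <- c(paste0("PSD.", bands$name), "HP-activity", "HP-mobility",
           "HP-complexity", "SE", "HE", "KC", "HOC")
  desc <- data.frame(
    family = rep(sub("^PSD\\..*$", "PSD", fam), length(ch)),
    band = rep(ifelse(grepl("^PSD", fam), sub("^PSD\\.", "", fam), NA),
               length(ch)),
    channel = rep(ch, each = length(fam)))
  colnames(chvals) <- paste0(desc$family,
                             ifelse(is.na(desc$band), "",
                                    paste0(".", desc$band)),
                             ".", desc$channel)
  dimnames(covs) <- list(NULL, bands$name, ch, ch)
  structure(list(
    subject_id = subject_id, stream = stream, kept = kept,
    windows = windows, conc = conc_series,
    chfeat = list(values = chvals, desc = desc),
    covs = covs, channels = ch, montage = montage, bands = bands,
    rejection_ratio = mean(!kept)),
    class = "attention_subject")
}

#' Per-window feature series for a channel set
#'
#' Slices the prepared subject's cache: one value per feature per window,
#' the feature computed over the concatenated kept trials of the window.
#'
#' @param subject an `attention_subject`.
#' @param cs a [channel_set()].
#' @param csp_mode `"median"` fits CSP on a median split of the window
#'   CONC values (high vs low attention); `"none"` omits the CSP block.
#' @return A `feature_table` with one row per window.
#' @export
feature_window_series <- function(subject, cs,
                                  csp_mode = c("median", "none")) {
  csp_mode <- match.arg(csp_mode)
  cs <- channel_set(as.character(cs), subject$montage)
  missing <- setdiff(as.character(cs), subject$channels)
  if (length(missing)) {
    stop("channel(s) missing from subject data: ",
         paste(missing, collapse = ", "))
  }
  csp_blk <- NULL
  if (csp_mode == "median") {
    ok <- !is.na(subject$conc)
    split_lab <- ifelse(subject$conc > median(subject$conc[ok]),
                        "high", "low")
    idx <- match(as.character(cs), dimnames(subject$covs)[[3]])
    covs <- subject$covs[, , idx, idx, drop = FALSE]
    if (sum(split_lab[ok] == "high") >= 2 &&
        sum(split_lab[ok] == "low") >= 2) {
      classes <- c("high", "low")
      models <- lapply(classes, function(cl) {
        lapply(seq_len(nrow(subject$bands)), function(b) {
          fit_csp_from_covs(covs[ok, b, , , drop = FALSE],
                            split_lab[ok], cl, subject$bands[b, ],
                            as.character(cs))
        })
      })
      names(models) <- classes
      csp_blk <- csp_feature_block(covs, models, classes, subject$bands)
    } else {
      warning("too few windows on one side of the CONC median split; ",
              "CSP block omitted")
    }
  }
  assemble_battery(subject$chfeat, cs, subject$montage, subject$bands,
                   csp_blk)
}

#' Evaluate one electrode configuration on the attention task
#'
#' For each subject, correlates every feature's window series with the
#' CONC series and takes the largest absolute correlation coefficient;
#' the configuration's score is the mean of these maxima over subjects.
#'
#' @param cs a [channel_set()].
#' @param subjects list of [prepare_attention_subject()] objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param csp_mode passed to [feature_window_series()].
#' @return List with `per_subject` data frame (subject, best_abs_r,
#'   best_feature) and `mean_abs_r`.
#' @export
evaluate_config_attention <- function(cs, subjects, method = "pearson",
                                      csp_mode = "median") {
  if (!length(subjects)) stop("no subjects supplied")
  rows <- list()
  for (s in subjects) {
    ok <- !is.na(s$conc)
    if (sum(ok) < 3) {
      warning("subject ", s$subject_id,
              ": fewer than 3 usable windows; skipped")
      next
    }
    if (sd(s$conc[ok]) == 0) {
      warning("subject ", s$subject_id,
              ": zero-variance CONC series; skipped")
      next
    }
    ft <- feature_window_series(s, cs, csp_mode)
    r <- suppressWarnings(
      cor(ft$values[ok, , drop = FALSE], s$conc[ok], method = method))
    if (all(is.na(r))) {
      warning("subject ", s$subject_id,
              ": all feature series degenerate; skipped")
      next
    }
    best <- which.max(abs(r))
    rows[[length(rows) + 1L]] <-
      data.frame(subject = s$subject_id, best_abs_r = abs(r[best]),
                 best_feature = colnames(ft$values)[best])
  }
  if (!length(rows)) stop("no usable subjects")
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean_abs_r = mean(per_subject$best_abs_r))
}
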