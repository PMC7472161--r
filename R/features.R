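#' Default spectral sub-bands
#'
#' delta 1-4, theta 4-8, alpha 8-13, low beta 13-22, high beta 22-30 and
#' gamma 30-50 Hz. Band intervals are half-open `[low, high)` when mapped
#' to DFT bins.
#'
#' @return data frame with columns `name`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "lbeta", "hbeta", "gamma"),
             low  = c(1, 4, 8, 13, 22, 30),
             high = c(4, 8, 13, 22, 30, 50))
}

# DFT bin indices (1-based, positive-frequency half, DC excluded) whose
# frequency lies in [low, high).
band_bins <- function(n, fs, low, high) {
  f <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2) + 1)
  half[f[half] >= low & f[half] < high]
}

#' Band power from the periodogram
#'
#' Mean of the `|DFT|^2 / N` periodogram over the DFT bins whose frequency
#' lies in `[low, high)`.
#'
#' @param x numeric signal of length >= 2.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz), within Nyquist.
#' @return Non-negative power value.
#' @export
band_psd <- function(x, fs, low, high) {
  n <- length(x)
  if (n < 2) stop("signal too short")
  if (high > fs / 2) stop("band exceeds Nyquist")
  bins <- band_bins(n, fs, low, high)
  if (!length(bins)) {
    stop("no DFT bin falls in [", low, ", ", high, ") Hz at N = ", n,
         ", fs = ", fs, "; use a longer window")
  }
  p <- Mod(fft(x))^2 / n
  mean(p[bins])
}

#' Differential and rational asymmetry
#'
#' DASM is the difference, RASM the ratio, of band powers at the left and
#' right members of an interhemispheric electrode pair.
#'
#' @param psd_left,psd_right band powers of the two pair members.
#' @param eps guard added to a zero right-hemisphere power in `rasm`
#'   (with a warning); set `eps = 0` to error instead.
#' @return Numeric value.
#' @export
dasm <- function(psd_left, psd_right) psd_left - psd_right

#' @rdname dasm
#' @export
rasm <- function(psd_left, psd_right, eps = 1e-12) {
  zero <- psd_right == 0
  if (any(zero)) {
    if (eps <= 0) stop("zero right-hemisphere power in RASM")
    warning("zero right-hemisphere power in RASM; epsilon guard applied")
    psd_right[zero] <- eps
  }
  psd_left / psd_right
}

#' Hjorth parameters
#'
#' Activity is the signal variance; mobility the ratio of the standard
#' deviation of the first difference to that of the signal; complexity the
#' ratio of the mobility of the first difference to the mobility of the
#' signal. A constant signal returns `c(0, 0, 0)` with attribute
#' `degenerate = TRUE` rather than NaN.
#'
#' @param x numeric signal of length >= 3.
#' @return Named vector `(activity, mobility, complexity)`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  s0 <- sd(x)
  if (s0 == 0) {
    return(structure(c(activity = 0, mobility = 0, complexity = 0),
                     degenerate = TRUE))
  }
  d1 <- diff(x); d2 <- diff(d1)
  s1 <- sd(d1); s2 <- sd(d2)
  mob <- s1 / s0
  comp <- if (s1 == 0) 0 else (s2 / s1) / mob
  c(activity = s0^2, mobility = mob, complexity = comp)
}

#' Shannon entropy of the amplitude histogram
#'
#' Amplitudes are binned into `n_bins` equal-width bins spanning the
#' signal's min-max range; the entropy of the bin occupancy probabilities
#' is returned in nats (empty bins contribute zero). Range `[0, ln n_bins]`.
#'
#' @param x numeric signal with `length(x) >= n_bins`.
#' @param n_bins number of amplitude bins (default 16).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(x, n_bins = 16) {
  if (length(x) < n_bins) stop("need at least n_bins samples")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  idx <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(idx, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Hurst exponent by single-scale rescaled range
#'
#' With `z` the cumulative sum of mean deviations, `R = max(z) - min(z)`
#' and `S` the standard deviation of the signal, returns
#' `log(R / S) / log(N)`. Values outside `[0, 1.5]` are clipped with a
#' warning; a constant signal returns 0 with attribute `degenerate`.
#'
#' @param x numeric signal of length >= 20.
#' @return Hurst estimate in `[0, 1.5]`.
#' @export
hurst_rs <- function(x) {
  n <- length(x)
  if (n < 20) stop("need at least 20 samples")
  s <- sd(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  z <- cumsum(x - mean(x))
  r <- max(z) - min(z)
  h <- log(r / s) / log(n)
  if (h < 0 || h > 1.5) {
    warning("Hurst estimate ", signif(h, 3), " outside [0, 1.5]; clipped")
    h <- min(max(h, 0), 1.5)
  }
  h
}

#' Kolmogorov complexity via Lempel-Ziv (1976)
#'
#' The signal is binarized at its median; `c(n)` is the LZ76
#' distinct-phrase count of the binary string and `b(n) = n / log2(n)` its
#' asymptotic value for a random string. Returns `c(n) / b(n)`, which
#' approaches 1 for incompressible sequences and 0 for trivial ones.
#'
#' @param x numeric signal of length >= 10.
#' @return Normalized complexity.
#' @export
kolmogorov_lz <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  bits <- as.integer(x > median(x))
  .lz76_binary(bits) / (n / log2(n))
}

#' Third-order cumulant at a lag pair
#'
#' Sample third-order moment `mean(y[k] * y[k+m] * y[k+n])` of the
#' mean-removed signal `y`, over all valid `k`. Defaults to lags (1, 2).
#'
#' @param x numeric signal with `length(x) > max(lag_m, lag_n)`.
#' @param lag_m,lag_n non-negative integer lags.
#' @return Cumulant value.
#' @export
hoc <- function(x, lag_m = 1, lag_n = 2) {
  n <- length(x)
  mx <- max(lag_m, lag_n)
  if (n <= mx) stop("signal shorter than the largest lag")
  y <- x - mean(x)
  k <- seq_len(n - mx)
  mean(y[k] * y[k + lag_m] * y[k + lag_n])
}

# ---------------------------------------------------------------------------
# Vectorized per-channel battery internals.
# X: samples x M matrix whose columns are (epoch, channel) signals.
# Returns a 13 x M matrix: 6 band powers, 3 Hjorth, SE, HE, KC, HOC.
channel_feature_block <- function(X, fs, bands = eeg_bands(), n_bins = 16,
                                  hoc_lags = c(1, 2),
                                  kc_max_samples = Inf) {
  n <- nrow(X); m <- ncol(X)
  FT <- stats::mvfft(X)
  P <- Mod(FT)^2 / n
  psd <- matrix(NA_real_, nrow(bands), m)
  for (b in seq_len(nrow(bands))) {
    bins <- band_bins(n, fs, bands$low[b], bands$high[b])
    if (!length(bins)) {
      stop("band ", bands$name[b], " has no DFT bin at N = ", n,
           ", fs = ", fs, "; use a longer window")
    }
    psd[b, ] <- if (length(bins) == 1) P[bins, ] else colMeans(P[bins, ,
                                                                 drop = FALSE])
  }
  mu <- colMeans(X)
  Y <- sweep(X, 2, mu)
  s0 <- sqrt(colSums(Y^2) / (n - 1))
  D1 <- X[-1, , drop = FALSE] - X[-n, , drop = FALSE]
  D2 <- D1[-1, , drop = FALSE] - D1[-(n - 1), , drop = FALSE]
  s1 <- apply(D1, 2, sd)
  s2 <- apply(D2, 2, sd)
  mob <- ifelse(s0 > 0, s1 / s0, 0)
  comp <- ifelse(s1 > 0 & s0 > 0, (s2 / s1) / mob, 0)
  act <- s0^2
  # Shannon entropy: shared vectorized binning
  rmin <- apply(X, 2, min); rmax <- apply(X, 2, max)
  width <- rmax - rmin
  se <- numeric(m)
  ok <- width > 0
  if (any(ok)) {
    Z <- sweep(sweep(X[, ok, drop = FALSE], 2, rmin[ok]), 2, width[ok], "/")
    idx <- pmin(floor(Z * n_bins) + 1L, n_bins)
    off <- matrix(rep((seq_len(sum(ok)) - 1L) * n_bins, each = n),
                  nrow = n)
    cnt <- tabulate(idx + off, n_bins * sum(ok)) / n
    cntm <- matrix(cnt, nrow = n_bins)
    se[ok] <- -colSums(ifelse(cntm > 0, cntm * log(cntm), 0))
  }
  # Hurst
  Zc <- apply(Y, 2, cumsum)
  rr <- apply(Zc, 2, max) - apply(Zc, 2, min)
  he <- ifelse(s0 > 0, pmin(pmax(log(rr / s0) / log(n), 0), 1.5), 0)
  # Kolmogorov (LZ76 in C++); on very long segments the quadratic scan is
  # capped to a leading sub-segment (the normalized estimate is stable in n)
  n_kc <- min(n, kc_max_samples)
  kc <- .lz76_columns(X[seq_len(n_kc), , drop = FALSE]) /
    (n_kc / log2(n_kc))
  # HOC
  mx <- max(hoc_lags)
  k <- seq_len(n - mx)
  hc <- colMeans(Y[k, , drop = FALSE] * Y[k + hoc_lags[1], , drop = FALSE] *
                   Y[k + hoc_lags[2], , drop = FALSE])
  out <- rbind(psd, act, mob, comp, se, he, kc, hc)
  rownames(out) <- c(paste0("PSD.", bands$name), "HP-activity",
                     "HP-mobility", "HP-complexity", "SE", "HE", "KC", "HOC")
  out
}

# Per-channel features for every (epoch, channel) of an epoched recording.
# Returns list(values = n_kept x (n_ch * 13) matrix, desc = data.frame).
channel_features <- function(er, channels = er$labels, bands = eeg_bands(),
                             n_bins = 16, hoc_lags = c(1, 2),
                             kept_only = TRUE) {
  ch_idx <- match(canonical_label(channels), er$labels)
  if (anyNA(ch_idx)) {
    stop("channel(s) missing from recording: ",
         paste(channels[is.na(ch_idx)], collapse = ", "))
  }
  keep <- if (kept_only) which(er$meta$kept) else seq_len(dim(er$epochs)[1])
  n_ep <- length(keep); n_ch <- length(ch_idx); n <- dim(er$epochs)[3]
  # columns: epoch-major within channel (channel blocks)
  X <- matrix(NA_real_, n, n_ep * n_ch)
  for (j in seq_len(n_ch)) {
    X[, (j - 1) * n_ep + seq_len(n_ep)] <-
      t(er$epochs[keep, ch_idx[j], , drop = FALSE][, 1, ])
  }
  blk <- channel_feature_block(X, er$fs, bands, n_bins, hoc_lags)
  n_feat <- nrow(blk)
  vals <- matrix(NA_real_, n_ep, n_ch * n_feat)
  desc <- data.frame(family = character(0), band = character(0),
                     channel = character(0))
  fam <- sub("^PSD\\..*$", "PSD", rownames(blk))
  bnd <- ifelse(fam == "PSD", sub("^PSD\\.", "", rownames(blk)), NA)
  for (j in seq_len(n_ch)) {
    cols <- (j - 1) * n_feat + seq_len(n_feat)
    vals[, cols] <- t(blk[, (j - 1) * n_ep + seq_len(n_ep), drop = FALSE])
    desc <- rbind(desc, data.frame(family = fam, band = bnd,
                                   channel = er$labels[ch_idx[j]]))
  }
  colnames(vals) <- paste0(desc$family,
                           ifelse(is.na(desc$band), "", paste0(".", desc$band)),
                           ".", desc$channel)
  list(values = vals, desc = desc, epochs_used = keep)
}

# ---------------------------------------------------------------------------
# Band-limited epoch covariances via DFT masking (ideal band selection):
# returns array [n_obs, n_band, n_ch, n_ch]. The covariance of the
# band-filtered epoch equals the cross-spectral sum over the band's bins
# (both frequency half-planes), by Parseval.
band_covariances <- function(er, bands = eeg_bands(),
                             channels = er$labels, kept_only = TRUE) {
  ch_idx <- match(canonical_label(channels), er$labels)
  if (anyNA(ch_idx)) stop("channel(s) missing from recording")
  keep <- if (kept_only) which(er$meta$kept) else seq_len(dim(er$epochs)[1])
  n <- dim(er$epochs)[3]; n_ch <- length(ch_idx); n_b <- nrow(bands)
  masks <- lapply(seq_len(n_b), function(b) {
    pos <- band_bins(n, er$fs, bands$low[b], bands$high[b])
    mir <- n + 2L - pos
    mir <- mir[mir > floor(n / 2) + 1 & mir <= n]
    c(pos, mir)
  })
  out <- array(NA_real_, c(length(keep), n_b, n_ch, n_ch))
  for (i in seq_along(keep)) {
    Xe <- t(er$epochs[keep[i], ch_idx, , drop = FALSE][1, , ])
    Fe <- stats::mvfft(Xe)
    for (b in seq_len(n_b)) {
      Fb <- Fe[masks[[b]], , drop = FALSE]
      out[i, b, , ] <- Re(crossprod(Conj(Fb), Fb)) / (n * n)
    }
  }
  dimnames(out) <- list(NULL, bands$name, er$labels[ch_idx],
                        er$labels[ch_idx])
  out
}

# Fit one CSP filter pair from class-average covariances. Solves the
# generalized eigenproblem of C_target against C_target + C_rest by
# whitening; keeps the eigenvectors with the largest and smallest
# eigenvalue (2m = 2 spatial filters).
csp_fit_cov <- function(cov_target, cov_rest) {
  nch <- nrow(cov_target)
  ctot <- cov_target + cov_rest
  ev <- eigen(ctot, symmetric = TRUE)
  tol <- 1e-10 * max(ev$values, 0)
  if (any(ev$values <= tol)) {
    warning("rank-deficient covariance; ridge regularization applied")
    lambda <- 1e-6 * sum(diag(ctot)) / nch
    ctot <- ctot + diag(lambda, nch)
    ev <- eigen(ctot, symmetric = TRUE)
  }
  Pw <- diag(1 / sqrt(ev$values), nch) %*% t(ev$vectors)
  S <- Pw %*% cov_target %*% t(Pw)
  S <- (S + t(S)) / 2
  e2 <- eigen(S, symmetric = TRUE)
  W <- t(Pw) %*% e2$vectors[, c(1L, nch), drop = FALSE]
  # sign convention: largest-magnitude row positive (features are
  # sign-invariant; this fixes reproducibility of the filters themselves)
  for (p in 1:2) {
    j <- which.max(abs(W[, p]))
    if (W[j, p] < 0) W[, p] <- -W[, p]
  }
  list(W = W, eigenvalues = e2$values[c(1L, nch)])
}

#' Fit a common spatial pattern model
#'
#' One-vs-rest CSP for one class and one frequency band: the target-class
#' and rest-class covariances are averages of trace-normalized band-limited
#' epoch covariances; the generalized eigenproblem of the target covariance
#' against their sum yields the spatial filters, of which the
#' largest- and smallest-eigenvalue eigenvectors are kept (2 filters).
#'
#' @param er an `epoched_recording` (kept epochs are used).
#' @param y per-kept-epoch class labels.
#' @param band one-row data frame (or list) with `low`/`high` in Hz.
#' @param target_class the class the filters discriminate from the rest.
#' @param channels channels entering the model.
#' @return A `csp_model`: filters `W` (channels x 2), eigenvalues, band,
#'   class and channel labels.
#' @export
csp_fit <- function(er, y, band, target_class, channels = er$labels) {
  bands1 <- data.frame(name = "band", low = band$low, high = band$high)
  covs <- band_covariances(er, bands1, channels)
  fit_csp_from_covs(covs[, 1, , , drop = FALSE], y, target_class,
                    band, canonical_label(channels))
}

fit_csp_from_covs <- function(covs, y, target_class, band, channels) {
  covs <- array(covs, dim(covs)[c(1, 3, 4)])
  if (sum(y == target_class) < 2 || sum(y != target_class) < 2) {
    stop("need at least 2 epochs on each side of the one-vs-rest split")
  }
  tr <- apply(covs, 1, function(C) sum(diag(C)))
  tr[tr == 0] <- 1
  normed <- sweep(covs, 1, tr, "/")
  ct <- apply(normed[y == target_class, , , drop = FALSE], c(2, 3), mean)
  cr <- apply(normed[y != target_class, , , drop = FALSE], c(2, 3), mean)
  fit <- csp_fit_cov(ct, cr)
  structure(list(W = fit$W, eigenvalues = fit$eigenvalues, band = band,
                 target_class = target_class, channels = channels),
            class = "csp_model")
}

#' Compute CSP features for one epoch
#'
#' Band-filters the epoch, applies the model's spatial filters and returns
#' `log(var(Z_p) / sum_i var(Z_i))` for each of the two filters.
#'
#' @param model a `csp_model` from [csp_fit()].
#' @param epoch channels x samples matrix (channel order must match the
#'   model's `channels`).
#' @param fs sampling rate (Hz).
#' @return Numeric vector of length 2.
#' @export
csp_features <- function(model, epoch, fs) {
  n <- ncol(epoch)
  bins <- band_bins(n, fs, model$band$low, model$band$high)
  FT <- stats::mvfft(t(epoch))
  mir <- n + 2L - bins
  mir <- mir[mir > floor(n / 2) + 1 & mir <= n]
  Fb <- FT[c(bins, mir), , drop = FALSE]
  C <- Re(crossprod(Conj(Fb), Fb)) / (n * n)
  v <- diag(t(model$W) %*% C %*% model$W)
  log(v / sum(v))
}

# CSP feature block for many observations from precomputed band covariances.
# models: list over classes of lists over bands of csp_model (or W only).
# covs: [n_obs, n_band, ch, ch]. Returns n_obs x (n_class * n_band * 2).
csp_feature_block <- function(covs, models, classes, bands) {
  n_obs <- dim(covs)[1]
  n_b <- nrow(bands)
  out <- matrix(NA_real_, n_obs, length(classes) * n_b * 2)
  desc <- data.frame(family = character(0), band = character(0),
                     channel = character(0), class = character(0))
  col <- 0L
  for (cl in classes) {
    for (b in seq_len(n_b)) {
      W <- models[[cl]][[b]]$W
      v1 <- numeric(n_obs); v2 <- numeric(n_obs)
      for (i in seq_len(n_obs)) {
        C <- covs[i, b, , ]
        q <- diag(t(W) %*% C %*% W)
        v1[i] <- q[1]; v2[i] <- q[2]
      }
      tot <- v1 + v2
      tot[tot <= 0] <- .Machine$double.eps
      v1 <- pmax(v1, .Machine$double.xmin)
      v2 <- pmax(v2, .Machine$double.xmin)
      out[, col + 1L] <- log(v1 / tot)
      out[, col + 2L] <- log(v2 / tot)
      desc <- rbind(desc,
                    data.frame(family = "CSP", band = bands$name[b],
                               channel = NA, class = cl)[c(1, 1), ])
      col <- col + 2L
    }
  }
  colnames(out) <- paste0("CSP.", rep(classes, each = n_b * 2), ".",
                          rep(rep(bands$name, each = 2), length(classes)),
                          ".", rep(1:2, length(classes) * n_b))
  list(values = out, desc = desc)
}

# Assemble the full battery for a channel set from a per-channel feature
# cache (channel_features() output) plus an optional CSP block.
# Column order: PSD, DASM, RASM, Hjorth, SE, HE, KC, HOC, CSP.
assemble_battery <- function(chfeat, cs, montage, bands = eeg_bands(),
                             csp = NULL) {
  ch <- as.character(cs)
  desc <- chfeat$desc
  pick <- function(fam) unlist(lapply(ch, function(c1)
    which(desc$family == fam & desc$channel == c1)))
  psd_cols <- pick("PSD")
  other_cols <- unlist(lapply(c("HP-activity", "HP-mobility",
                                "HP-complexity", "SE", "HE", "KC", "HOC"),
                              pick))
  prs <- interhemispheric_pairs(cs, montage)
  avals <- NULL; adesc <- NULL
  if (nrow(prs)) {
    blocks <- list()
    for (asym in c("DASM", "RASM")) {
      for (r in seq_len(nrow(prs))) {
        li <- which(desc$family == "PSD" & desc$channel == prs[r, 1])
        ri <- which(desc$family == "PSD" & desc$channel == prs[r, 2])
        block <- if (asym == "DASM") {
          chfeat$values[, li, drop = FALSE] -
            chfeat$values[, ri, drop = FALSE]
        } else {
          rasm(chfeat$values[, li, drop = FALSE],
               chfeat$values[, ri, drop = FALSE])
        }
        pr_name <- paste0(prs[r, 1], "-", prs[r, 2])
        colnames(block) <- paste0(asym, ".", desc$band[li], ".", pr_name)
        blocks[[length(blocks) + 1L]] <-
          list(vals = block,
               desc = data.frame(family = asym, band = desc$band[li],
                                 channel = pr_name))
      }
    }
    avals <- do.call(cbind, lapply(blocks, `[[`, "vals"))
    adesc <- do.call(rbind, lapply(blocks, `[[`, "desc"))
    adesc$class <- NA
  }
  d_psd <- desc[psd_cols, ]; d_psd$class <- NA
  d_oth <- desc[other_cols, ]; d_oth$class <- NA
  vals <- cbind(chfeat$values[, psd_cols, drop = FALSE], avals,
                chfeat$values[, other_cols, drop = FALSE])
  d <- rbind(d_psd, adesc, d_oth)
  if (!is.null(csp)) {
    vals <- cbind(vals, csp$values)
    d <- rbind(d, csp$desc)
  }
  rownames(d) <- NULL
  structure(list(values = vals, desc = d), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " epochs x ", ncol(x$values),
      " features (", paste(unique(x$desc$family), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Extract the full feature battery for a channel set
#'
#' Computes, per kept epoch: per-band power (PSD) for every channel, DASM
#' and RASM for every interhemispheric pair in the set, the three Hjorth
#' parameters, Shannon entropy, Hurst exponent, Kolmogorov (LZ76)
#' complexity and the lag-(1,2) third-order cumulant per channel, and the
#' filter-bank CSP features (2 per band per class). The column count equals
#' [count_features()] for the same set.
#'
#' When `csp_models` is `NULL` and the recording carries class labels, CSP
#' models are fitted on all kept epochs; inside cross-validation use the
#' evaluator functions, which refit CSP within each training fold.
#'
#' @param er an `epoched_recording`.
#' @param cs a [channel_set()].
#' @param montage the montage defining pair structure.
#' @param bands band definitions ([eeg_bands()]).
#' @param csp_models optional precomputed CSP models (list over classes of
#'   lists over bands); `FALSE` omits the CSP block entirely.
#' @param n_bins Shannon-entropy bins.
#' @param hoc_lags third-order cumulant lags.
#' @return A `feature_table`: `values` (kept epochs x features) and `desc`
#'   (per-feature family, band, channel, class).
#' @export
extract_battery <- function(er, cs, montage = default_montage(),
                            bands = eeg_bands(), csp_models = NULL,
                            n_bins = 16, hoc_lags = c(1, 2)) {
  cs <- channel_set(as.character(cs), montage)
  chfeat <- channel_features(er, cs, bands, n_bins, hoc_lags)
  csp_blk <- NULL
  if (!identical(csp_models, FALSE)) {
    y <- er$meta$class[er$meta$kept]
    if (is.null(csp_models)) {
      if (all(is.na(y))) {
        stop("no class labels available to fit CSP models; pass ",
             "`csp_models` or `csp_models = FALSE`")
      }
      covs <- band_covariances(er, bands, cs)
      classes <- sort(unique(y))
      csp_models <- lapply(classes, function(cl) {
        lapply(seq_len(nrow(bands)), function(b) {
          fit_csp_from_covs(covs[, b, , , drop = FALSE], y, cl,
                            bands[b, ], as.character(cs))
        })
      })
      names(csp_models) <- classes
    } else {
      covs <- band_covariances(er, bands, cs)
      classes <- names(csp_models)
    }
    csp_blk <- csp_feature_block(covs, csp_models, classes, bands)
  }
  ft <- assemble_battery(chfeat, cs, montage, bands, csp_blk)
  if (any(!is.finite(ft$values))) {
    stop("non-finite feature values produced from finite input")
  }
  ft
}
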