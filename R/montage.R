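#' Electrode montages and symmetric channel sets
#'
#' A montage partitions an ordered set of 10-20 channel labels into midline
#' singletons (individually symmetric: they sit on the sagittal plane) and
#' left-right interhemispheric pairs. Hemispherically symmetric subsets are
#' those in which every lateral electrode appears together with its mirror
#' partner; such subsets are both mechanically convenient for headsets and
#' required for the asymmetry features (DASM/RASM).
#'
#' @param midline character vector of midline channel labels.
#' @param pairs list of length-2 character vectors `(left, right)`, or a
#'   two-column matrix.
#' @return An object of class `montage` with components `midline`, `pairs`
#'   (two-column character matrix) and `all_channels` (acquisition order:
#'   pair members interleaved first, then midline).
#' @examples
#' m <- default_montage()
#' length(m$all_channels)  # 32
#' @export
montage <- function(midline, pairs) {
  midline <- canonical_label(midline)
  if (is.list(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) canonical_label(p)))
  } else {
    pairs <- apply(as.matrix(pairs), c(1, 2), canonical_label)
  }
  if (!is.matrix(pairs) || ncol(pairs) != 2) {
    stop("`pairs` must be a list of (left, right) label pairs")
  }
  all <- c(as.vector(t(pairs)), midline)
  if (anyDuplicated(all)) {
    stop("duplicated channel label(s): ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  }
  structure(list(midline = midline, pairs = pairs, all_channels = all),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$all_channels), " channels: ",
      nrow(x$pairs), " pairs + ", length(x$midline), " midline (",
      paste(x$midline, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Canonical label form: trimmed, upper-case except a trailing lower-case 'z'
# (Fz, Cz, ...) and the 'p' in Fp1/Fp2, matching common 10-20 typography.
canonical_label <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("Z$", "z", x)
  x <- sub("^FP", "Fp", x)
  x
}

#' Default 32-channel symmetric montage
#'
#' The Biosemi-style 32-channel 10-20 montage: midline Fz, Cz, Pz, Oz plus
#' 14 interhemispheric pairs (Fp1-Fp2, AF3-AF4, F7-F8, F3-F4, FC5-FC6,
#' FC1-FC2, T7-T8, C3-C4, CP5-CP6, CP1-CP2, P7-P8, P3-P4, PO3-PO4, O1-O2).
#' Loaded from the packaged montage definition file.
#'
#' @return A [montage()] object.
#' @export
default_montage <- function() {
  read_montage(system.file("extdata", "montage_biosemi32.yaml",
                           package = "eegmontage"))
}

#' Read a montage definition file
#'
#' The file is YAML (or JSON, a YAML subset) with keys `midline` (list of
#' labels) and `pairs` (list of two-element lists).
#'
#' @param path path to the definition file.
#' @return A [montage()] object.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  def <- yaml::read_yaml(path)
  if (!all(c("midline", "pairs") %in% names(def))) {
    stop("montage file must define `midline` and `pairs`")
  }
  montage(unlist(def$midline), def$pairs)
}

#' Construct a channel set against a montage
#'
#' @param channels character vector of channel labels (case-insensitive).
#' @param montage a [montage()] object.
#' @param check_symmetry error if the set violates hemispherical symmetry.
#' @return Character vector of canonical labels, class `channel_set`.
#' @export
channel_set <- function(channels, montage = default_montage(),
                        check_symmetry = TRUE) {
  ch <- canonical_label(channels)
  unknown <- setdiff(ch, montage$all_channels)
  if (length(unknown)) {
    stop("channel(s) not in montage: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(ch)) stop("duplicated channels in set")
  # keep montage acquisition order
  ch <- montage$all_channels[montage$all_channels %in% ch]
  if (check_symmetry) {
    up <- unpaired_channels(ch, montage)
    if (length(up)) {
      stop("channel set is not hemispherically symmetric; unpaired: ",
           paste(up, collapse = ", "))
    }
  }
  structure(ch, class = "channel_set")
}

# Lateral members whose mirror partner is missing from `channels`.
unpaired_channels <- function(channels, montage) {
  bad <- character(0)
  for (r in seq_len(nrow(montage$pairs))) {
    p <- montage$pairs[r, ]
    inset <- p %in% channels
    if (xor(inset[1], inset[2])) bad <- c(bad, p[inset])
  }
  bad
}

#' Test hemispherical symmetry of a channel subset
#'
#' @param channels character vector of labels.
#' @param montage a [montage()] object.
#' @return `TRUE` iff every lateral member's mirror partner is also present.
#' @export
is_symmetric_set <- function(channels, montage = default_montage()) {
  length(unpaired_channels(canonical_label(channels), montage)) == 0
}

#' Interhemispheric pairs fully contained in a channel set
#'
#' Midline channels contribute no pairs. These pairs carry the DASM and
#' RASM asymmetry features.
#'
#' @param cs a [channel_set()] (or label vector).
#' @param montage a [montage()] object.
#' @return Two-column character matrix `(left, right)`, zero rows if none.
#' @export
interhemispheric_pairs <- function(cs, montage = default_montage()) {
  ch <- canonical_label(as.character(cs))
  up <- unpaired_channels(ch, montage)
  if (length(up)) {
    stop("channel set is not hemispherically symmetric; unpaired: ",
         paste(up, collapse = ", "))
  }
  keep <- montage$pairs[, 1] %in% ch & montage$pairs[, 2] %in% ch
  montage$pairs[keep, , drop = FALSE]
}

#' Enumerate all hemispherically symmetric electrode subsets of size k
#'
#' Every admissible subset is a union of p full pairs and m midline channels
#' with 2p + m = k. Enumeration order is deterministic: configurations with
#' more pairs come first, and within a fixed (p, m) split pairs and midline
#' combinations advance in montage order. This fixed order is the tie-break
#' for "first best configuration" in the montage search.
#'
#' @param montage a [montage()] object.
#' @param k even subset size, `2 <= k <= length(montage$all_channels)`.
#' @return List of [channel_set()] objects.
#' @examples
#' length(enumerate_symmetric_configs(default_montage(), 2))  # 20
#' @export
enumerate_symmetric_configs <- function(montage = default_montage(), k) {
  if (length(k) != 1 || k %% 2 != 0 || k < 2) {
    stop("k must be a single even number >= 2 (symmetric subsets have even ",
         "size); got ", paste(k, collapse = ","))
  }
  if (k > length(montage$all_channels)) {
    stop("k exceeds the number of montage channels")
  }
  n_pairs <- nrow(montage$pairs)
  n_mid <- length(montage$midline)
  out <- list()
  for (p in seq(min(k %/% 2, n_pairs), 0L)) {
    m <- k - 2L * p
    if (m > n_mid) next
    pair_combos <- if (p == 0) list(integer(0)) else
      asplit(combn(n_pairs, p), 2)
    mid_combos <- if (m == 0) list(integer(0)) else
      asplit(combn(n_mid, m), 2)
    for (pc in pair_combos) {
      pair_ch <- as.vector(t(montage$pairs[pc, , drop = FALSE]))
      for (mc in mid_combos) {
        ch <- c(pair_ch, montage$midline[mc])
        out[[length(out) + 1L]] <-
          channel_set(ch, montage, check_symmetry = FALSE)
      }
    }
  }
  out
}

#' Feature counting rule for the battery
#'
#' Encodes how many feature columns the battery produces for a channel set:
#' per-band power (PSD) per channel, per-band DASM and RASM per pair,
#' 3 Hjorth parameters plus 4 scalar families (Shannon entropy, Hurst
#' exponent, Kolmogorov complexity, higher-order cumulant) per channel, and
#' a fixed per-class CSP block (2 filters x 6 bands = 12 per class by
#' default, independent of channel count).
#'
#' @param n_bands number of spectral sub-bands (default 6).
#' @param n_hp Hjorth parameters per channel (3).
#' @param n_scalar_families entropy/complexity families per channel (4).
#' @param n_csp_per_class CSP features per class (12).
#' @param n_classes number of classes (4).
#' @return A list of class `feature_count_rule`.
#' @export
feature_count_rule <- function(n_bands = 6, n_hp = 3, n_scalar_families = 4,
                               n_csp_per_class = 12, n_classes = 4) {
  counts <- c(n_bands, n_hp, n_scalar_families, n_csp_per_class, n_classes)
  if (any(counts <= 0)) stop("all counts must be positive")
  structure(list(n_bands = n_bands, n_hp = n_hp,
                 n_scalar_families = n_scalar_families,
                 n_csp_per_class = n_csp_per_class, n_classes = n_classes),
            class = "feature_count_rule")
}

#' Count the feature battery size for a channel set
#'
#' For the full 32-channel montage the default rule gives
#' 6x32 + 6x14 + 6x14 + (3+4)x32 + 12x4 = 632 features; for the 6-channel
#' set CP1, CP2, O1, O2, F7, F8 it gives 162.
#'
#' @param cs a [channel_set()] (or label vector).
#' @param rule a [feature_count_rule()].
#' @param montage the montage defining the pair structure.
#' @return Integer feature count.
#' @export
count_features <- function(cs, rule = feature_count_rule(),
                           montage = default_montage()) {
  ch <- canonical_label(as.character(cs))
  n_ch <- length(ch)
  n_pr <- nrow(interhemispheric_pairs(ch, montage))
  rule$n_bands * n_ch +                      # PSD
    2 * rule$n_bands * n_pr +                # DASM + RASM
    (rule$n_hp + rule$n_scalar_families) * n_ch +
    rule$n_csp_per_class * rule$n_classes    # CSP (channel-count free)
}
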