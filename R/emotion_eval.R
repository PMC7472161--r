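#' Multi-class Fisher score
#'
#' Ratio of between-class to within-class variance,
#' `sum_c n_c (mu_c - mu)^2 / sum_c n_c sigma_c^2`, per feature column.
#' Non-negative, and invariant to affine transforms of the feature. Zero
#' within-class variance with distinct class means yields `Inf` (such a
#' feature ranks first); a globally constant feature scores 0.
#'
#' @param x numeric vector or epochs x features matrix.
#' @param y class labels (at least two classes present).
#' @return Numeric score per column.
#' @export
fisher_score <- function(x, y) {
  X <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  y <- droplevels(y)
  n_c <- as.vector(table(y))
  mu <- colMeans(X)
  mu_c <- rowsum(X, y) / n_c
  ss_c <- rowsum(X^2, y) / n_c
  var_c <- pmax(ss_c - mu_c^2, 0)     # population variance per class
  num <- colSums(n_c * sweep(mu_c, 2, mu)^2)
  den <- colSums(n_c * var_c)
  scale_ref <- colSums(sweep(X, 2, mu)^2) + .Machine$double.eps
  den_zero <- den <= 1e-12 * scale_ref
  out <- ifelse(den_zero, ifelse(num > 1e-12 * scale_ref, Inf, 0),
                num / den)
  unname(out)
}

#' Cross-validation specification
#'
#' @param n_folds number of folds (>= 2; default 10).
#' @param n_repeats number of repetitions (default 10).
#' @param stratified stratify folds by class?
#' @param seed RNG seed for fold assignment.
#' @return A list of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 10, n_repeats = 10, stratified = TRUE,
                    seed = 20160814) {
  if (n_folds < 2) stop("need at least 2 folds")
  if (n_repeats < 1) stop("need at least 1 repeat")
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 stratified = stratified, seed = seed), class = "cv_spec")
}

# Stratified (or plain) fold assignment for units with labels.
assign_folds <- function(y, n_folds, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

# Train a classifier on a selected feature matrix; returns a closure that
# predicts class labels for new rows. Features are standardized with
# training statistics.
fit_classifier <- function(X, y, classifier = c("svm", "lda", "dt")) {
  classifier <- match.arg(classifier)
  y <- factor(y)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  if (classifier == "svm") {
    fit <- e1071::svm(Z, y, kernel = "linear", cost = 1, scale = FALSE)
    function(newX) {
      as.character(predict(fit, sweep(sweep(newX, 2, mu), 2, s, "/")))
    }
  } else if (classifier == "lda") {
    fit <- suppressWarnings(MASS::lda(Z, grouping = y, tol = 1e-8))
    function(newX) {
      as.character(predict(fit,
                           sweep(sweep(newX, 2, mu), 2, s, "/"))$class)
    }
  } else {
    df <- data.frame(Z); df$.y <- y
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
    function(newX) {
      nd <- data.frame(sweep(sweep(newX, 2, mu), 2, s, "/"))
      colnames(nd) <- colnames(df)[seq_len(ncol(newX))]
      as.character(predict(fit, nd, type = "class"))
    }
  }
}

#' Select features by Fisher score
#'
#' Ranks columns by [fisher_score()] (stable order under ties). In
#' `"fixed"` mode the top `max_k` columns are returned. In `"nested"` mode
#' (the default) nested prefixes top-1 ... top-`max_k` are scored by inner
#' cross-validated accuracy on the supplied data only, and the best prefix
#' is returned, ties broken toward fewer features.
#'
#' @param X epochs x features matrix (training data only).
#' @param y per-epoch class labels.
#' @param max_k maximum number of features (default 20).
#' @param mode `"nested"` or `"fixed"`.
#' @param trial optional per-epoch trial ids; inner folds split at the
#'   trial level when given.
#' @param inner_folds folds for the nested mode's inner CV.
#' @param classifier classifier used by the nested mode.
#' @return Integer vector of selected column indices, best-ranked first.
#' @export
select_features <- function(X, y, max_k = 20, mode = c("nested", "fixed"),
                            trial = NULL, inner_folds = 3,
                            classifier = "svm") {
  mode <- match.arg(mode)
  if (ncol(X) < 1) stop("no feature columns to select from")
  ranking <- order(fisher_score(X, y), decreasing = TRUE)
  kmax <- min(max_k, ncol(X))
  if (mode == "fixed") return(ranking[seq_len(kmax)])
  if (is.null(trial)) trial <- seq_along(y)
  units <- unique(trial)
  uy <- y[match(units, trial)]
  fold <- assign_folds(uy, min(inner_folds, length(units)))
  acc <- matrix(NA_real_, max(fold), kmax)
  for (f in sort(unique(fold))) {
    tr <- trial %in% units[fold != f]
    te <- !tr
    if (length(unique(y[tr])) < 2 || !any(te)) next
    for (k in seq_len(kmax)) {
      sel <- ranking[seq_len(k)]
      pred <- fit_classifier(X[tr, sel, drop = FALSE], y[tr],
                             classifier)(X[te, sel, drop = FALSE])
      acc[f, k] <- mean(pred == y[te])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best_k <- which.max(mean_acc)   # first max: ties toward fewer features
  ranking[seq_len(best_k)]
}

#' Prepare a subject's emotion data for configuration evaluation
#'
#' Computes, once per subject, the per-channel feature cache and the
#' band-limited epoch covariances for all montage channels present in the
#' recording. Evaluating any channel set afterwards only slices this cache
#' and refits the (cheap) CSP models, which makes the exhaustive montage
#' search tractable.
#'
#' @param er an `epoched_recording` whose `meta$class` holds the per-epoch
#'   emotion labels.
#' @param subject_id identifier used in reports.
#' @param montage the montage.
#' @param bands band definitions.
#' @param n_bins,hoc_lags battery parameters (see [extract_battery()]).
#' @return An object of class `emotion_subject`.
#' @export
prepare_emotion_subject <- function(er, subject_id = "s1",
                                    montage = default_montage(),
                                    bands = eeg_bands(), n_bins = 16,
                                    hoc_lags = c(1, 2)) {
  ch <- intersect(montage$all_channels, er$labels)
  y <- er$meta$class[er$meta$kept]
  if (all(is.na(y))) stop("recording carries no class labels")
  structure(list(
    subject_id = subject_id,
    chfeat = channel_features(er, ch, bands, n_bins, hoc_lags),
    covs = band_covariances(er, bands, ch),
    y = y,
    trial = er$meta$trial[er$meta$kept],
    channels = ch, montage = montage, bands = bands),
    class = "emotion_subject")
}

# Assemble labeled features (non-CSP battery + covariance slab) for one
# channel set from a prepared subject.
labeled_features <- function(subject, cs) {
  cs <- channel_set(as.character(cs), subject$montage)
  missing <- setdiff(as.character(cs), subject$channels)
  if (length(missing)) {
    stop("channel(s) missing from subject data: ",
         paste(missing, collapse = ", "))
  }
  ft <- assemble_battery(subject$chfeat, cs, subject$montage,
                         subject$bands)
  idx <- match(as.character(cs), dimnames(subject$covs)[[3]])
  list(values = ft$values, desc = ft$desc,
       covs = subject$covs[, , idx, idx, drop = FALSE],
       y = subject$y, trial = subject$trial, cs = cs,
       bands = subject$bands)
}

#' Cross-validated classification accuracy for one channel set
#'
#' Repeated stratified k-fold cross-validation of the four-class emotion
#' classifier. Folds are split at the trial level by default, so epochs
#' from one trial never straddle the train/test boundary; predictions for
#' a test trial's epochs are combined by majority vote. Within each
#' training fold, CSP models are refitted and Fisher-score feature
#' selection is re-run — nothing is selected on test data (unless
#' `optimistic = TRUE`, which scores every nested prefix on the test fold
#' and keeps the best; this reproduces an optimistically biased
#' "highest achievable" protocol and is labeled as such).
#'
#' @param lf a prepared subject ([prepare_emotion_subject()]) together with
#'   a channel set: pass `subject` and `cs`, or a ready-made list from the
#'   internal assembly.
#' @param cs the [channel_set()] to evaluate.
#' @param cv a [cv_spec()].
#' @param classifier `"svm"` (linear, C = 1), `"lda"` or `"dt"`.
#' @param select `"nested"` or `"fixed"` Fisher selection.
#' @param max_k maximum selected features (default 20).
#' @param unit `"trial"` (majority vote) or `"epoch"` fold granularity.
#' @param optimistic choose the Fisher prefix on the test fold.
#' @return List: `accuracy` (mean over repeats x folds), `n_features`
#'   (mean selected), `fold_accuracies`.
#' @export
cv_accuracy <- function(lf, cs = NULL, cv = cv_spec(), classifier = "svm",
                        select = c("nested", "fixed"), max_k = 20,
                        unit = c("trial", "epoch"), optimistic = FALSE) {
  select <- match.arg(select)
  unit <- match.arg(unit)
  if (inherits(lf, "emotion_subject")) {
    if (is.null(cs)) stop("`cs` required with a prepared subject")
    lf <- labeled_features(lf, cs)
  }
  y <- lf$y
  trial <- if (unit == "trial") lf$trial else seq_along(y)
  classes <- sort(unique(y))
  units <- unique(trial)
  uy <- y[match(units, trial)]
  if (!is.null(cv$seed)) set.seed(cv$seed)
  accs <- c(); nfeat <- c()
  for (rep_i in seq_len(cv$n_repeats)) {
    fold <- assign_folds(uy, cv$n_folds, cv$stratified)
    for (f in sort(unique(fold))) {
      tr <- trial %in% units[fold != f]
      te <- trial %in% units[fold == f]
      if (length(unique(y[tr])) < length(classes) ||
          min(table(y[tr])) < 2) {
        warning("class absent or too sparse in a training fold; ",
                "fold skipped")
        next
      }
      models <- lapply(classes, function(cl) {
        lapply(seq_len(nrow(lf$bands)), function(b) {
          fit_csp_from_covs(lf$covs[tr, b, , , drop = FALSE], y[tr], cl,
                            lf$bands[b, ], dimnames(lf$covs)[[3]])
        })
      })
      names(models) <- classes
      cspX <- csp_feature_block(lf$covs, models, classes, lf$bands)$values
      X <- cbind(lf$values, cspX)
      if (optimistic) {
        ranking <- order(fisher_score(X[tr, , drop = FALSE], y[tr]),
                         decreasing = TRUE)
        best <- 0; best_n <- 1
        for (k in seq_len(min(max_k, ncol(X)))) {
          sel <- ranking[seq_len(k)]
          pred <- fit_classifier(X[tr, sel, drop = FALSE], y[tr],
                                 classifier)(X[te, sel, drop = FALSE])
          a <- unit_accuracy(pred, y[te], trial[te], unit)
          if (a > best) { best <- a; best_n <- k }
        }
        accs <- c(accs, best); nfeat <- c(nfeat, best_n)
      } else {
        sel <- select_features(X[tr, , drop = FALSE], y[tr], max_k,
                               mode = select, trial = trial[tr],
                               classifier = classifier)
        pred <- fit_classifier(X[tr, sel, drop = FALSE], y[tr],
                               classifier)(X[te, sel, drop = FALSE])
        accs <- c(accs, unit_accuracy(pred, y[te], trial[te], unit))
        nfeat <- c(nfeat, length(sel))
      }
    }
  }
  if (!length(accs)) stop("no usable folds (classes too sparse)")
  list(accuracy = mean(accs), n_features = mean(nfeat),
       fold_accuracies = accs)
}

# Accuracy at the chosen granularity: per epoch, or per trial after
# majority vote over the trial's epochs (ties broken by label order).
unit_accuracy <- function(pred, truth, trial, unit) {
  if (unit == "epoch") return(mean(pred == truth))
  ut <- unique(trial)
  correct <- vapply(ut, function(t) {
    p <- pred[trial == t]
    voted <- names(which.max(table(p)))
    voted == truth[trial == t][1]
  }, logical(1))
  mean(correct)
}

#' Evaluate one electrode configuration on the emotion task
#'
#' Runs [cv_accuracy()] for every prepared subject and averages the
#' accuracies; per-subject detail is retained for statistics.
#'
#' @param cs a [channel_set()].
#' @param subjects list of [prepare_emotion_subject()] objects.
#' @param cv a [cv_spec()]; the seed is offset per subject.
#' @param ... passed to [cv_accuracy()] (`classifier`, `select`, `max_k`,
#'   `unit`, `optimistic`).
#' @return List with `per_subject` data frame (subject, accuracy,
#'   n_features) and `mean_accuracy`.
#' @export
evaluate_config_emotion <- function(cs, subjects, cv = cv_spec(), ...) {
  if (!length(subjects)) stop("no subjects supplied")
  rows <- lapply(seq_along(subjects), function(i) {
    cvi <- cv
    if (!is.null(cvi$seed)) cvi$seed <- cvi$seed + i
    r <- cv_accuracy(subjects[[i]], cs, cv = cvi, ...)
    data.frame(subject = subjects[[i]]$subject_id,
               accuracy = r$accuracy, n_features = r$n_features)
  })
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean_accuracy = mean(per_subject$accuracy))
}
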