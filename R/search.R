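#' Generalized-configuration score
#'
#' `GCS = classification accuracy + |correlation coefficient|`, both
#' averaged across participants and each in `[0, 1]`, so the score lies in
#' `[0, 2]`. The GCS is the objective for general-purpose montages.
#'
#' @param mean_accuracy mean emotion-classification accuracy in `[0, 1]`.
#' @param mean_abs_r mean absolute attention correlation in `[0, 1]`.
#' @return Their sum.
#' @export
gcs <- function(mean_accuracy, mean_abs_r) {
  if (any(mean_accuracy < 0 | mean_accuracy > 1) ||
      any(mean_abs_r < 0 | mean_abs_r > 1)) {
    stop("both inputs must lie in [0, 1]")
  }
  mean_accuracy + mean_abs_r
}

#' Exhaustive symmetric-montage search
#'
#' Evaluates every hemispherically symmetric electrode configuration of
#' size `k` and ranks them by the design objective: mean emotion
#' classification accuracy (`"emotion"`), mean absolute attention
#' correlation (`"attention"`), or their sum, the GCS (`"general"`).
#' Ties break toward the earlier configuration in enumeration order.
#'
#' @param design `"emotion"`, `"attention"` or `"general"`.
#' @param k even configuration size.
#' @param emotion_subjects list of [prepare_emotion_subject()] objects
#'   (required for emotion and general designs).
#' @param attention_subjects list of [prepare_attention_subject()] objects
#'   (required for attention and general designs).
#' @param montage the montage searched over.
#' @param cv a [cv_spec()] for the emotion evaluations.
#' @param budget optional maximum number of configurations; when smaller
#'   than the enumeration, a seeded random subset is evaluated (with a
#'   warning — the search is then no longer exhaustive).
#' @param budget_seed seed for the budget subsample.
#' @param ... passed to [cv_accuracy()] / [evaluate_config_attention()]
#'   (`classifier`, `select`, `max_k`, `unit`, `method`, `csp_mode`).
#' @return A `design_result`: `best` channel set, `ranking` data frame
#'   (config, mean_accuracy, mean_abs_r, gcs, rank), and per-config
#'   per-subject detail.
#' @export
optimize_montage <- function(design = c("general", "emotion", "attention"),
                             k, emotion_subjects = NULL,
                             attention_subjects = NULL,
                             montage = default_montage(), cv = cv_spec(),
                             budget = NULL, budget_seed = 1, ...) {
  design <- match.arg(design)
  need_emo <- design %in% c("emotion", "general")
  need_att <- design %in% c("attention", "general")
  if (need_emo && !length(emotion_subjects)) {
    stop("the ", design, " design requires emotion_subjects")
  }
  if (need_att && !length(attention_subjects)) {
    stop("the ", design, " design requires attention_subjects")
  }
  configs <- enumerate_symmetric_configs(montage, k)
  if (!is.null(budget) && budget < length(configs)) {
    warning("budget ", budget, " < ", length(configs),
            " configurations; randomized subsample, search is not ",
            "exhaustive")
    set.seed(budget_seed)
    configs <- configs[sort(sample(length(configs), budget))]
  }
  dots <- list(...)
  emo_args <- dots[names(dots) %in%
                     c("classifier", "select", "max_k", "unit",
                       "optimistic")]
  att_args <- dots[names(dots) %in% c("method", "csp_mode")]
  n_cfg <- length(configs)
  acc <- rep(NA_real_, n_cfg); absr <- rep(NA_real_, n_cfg)
  detail <- vector("list", n_cfg)
  for (i in seq_len(n_cfg)) {
    cs <- configs[[i]]
    d <- list()
    if (need_emo) {
      ev <- do.call(evaluate_config_emotion,
                    c(list(cs = cs, subjects = emotion_subjects, cv = cv),
                      emo_args))
      acc[i] <- ev$mean_accuracy
      d$emotion <- ev$per_subject
    }
    if (need_att) {
      ev <- do.call(evaluate_config_attention,
                    c(list(cs = cs, subjects = attention_subjects),
                      att_args))
      absr[i] <- ev$mean_abs_r
      d$attention <- ev$per_subject
    }
    detail[[i]] <- d
  }
  score <- switch(design,
                  emotion = acc,
                  attention = absr,
                  general = gcs(acc, absr))
  labels <- vapply(configs, function(cs) paste(cs, collapse = "+"),
                   character(1))
  ranking <- data.frame(
    config = labels, k = k, mean_accuracy = acc, mean_abs_r = absr,
    gcs = if (design == "general") score else
      ifelse(is.na(acc) | is.na(absr), NA, acc + absr),
    score = score)
  ord <- order(-score, seq_len(n_cfg))   # stable: enumeration order breaks ties
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(n_cfg)
  rownames(ranking) <- NULL
  structure(list(design = design, k = k,
                 best = configs[[ord[1]]],
                 best_score = score[ord[1]],
                 ranking = ranking,
                 detail = detail[ord]),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", x$design, " design, k = ", x$k, "\n",
      "best: ", paste(x$best, collapse = " + "),
      " (score ", signif(x$best_score, 4), ")\n", sep = "")
  print(head(x$ranking, 5))
  invisible(x)
}

#' Compare montage designs statistically
#'
#' Paired comparison of per-subject metrics across designs: Friedman test
#' over all designs; when significant at `alpha`, all pairwise Wilcoxon
#' signed-rank tests with Bonferroni correction. A Kolmogorov-Smirnov
#' (Lilliefors) normality screen per design is reported alongside (the
#' rank-based tests are used because such metrics are typically
#' non-normal).
#'
#' @param metrics numeric matrix or data frame, subjects x designs (>= 2
#'   designs, >= 5 subjects), identically ordered subjects in every column.
#' @param alpha significance level gating the post-hoc tests.
#' @return A `design_comparison` list: `friedman` (chi-squared, df, p),
#'   `pairwise` data frame of Bonferroni-corrected Wilcoxon p-values (or
#'   `NULL`), `normality` per-design Lilliefors p-values.
#' @export
compare_designs <- function(metrics, alpha = 0.05) {
  m <- as.matrix(metrics)
  if (ncol(m) < 2) stop("need at least 2 designs")
  if (nrow(m) < 5) stop("need at least 5 subjects (paired tests)")
  if (anyNA(m)) stop("designs must have metrics for the same subjects")
  if (is.null(colnames(m))) colnames(m) <- paste0("design", seq_len(ncol(m)))
  all_tied <- all(apply(m, 1, function(r) length(unique(r)) == 1))
  fr <- if (all_tied) {
    list(statistic = c(`Friedman chi-squared` = 0),
         parameter = c(df = ncol(m) - 1), p.value = 1)
  } else {
    friedman.test(m)
  }
  pairwise <- NULL
  if (fr$p.value < alpha) {
    combs <- combn(ncol(m), 2)
    p_raw <- apply(combs, 2, function(ij) {
      suppressWarnings(
        wilcox.test(m[, ij[1]], m[, ij[2]], paired = TRUE))$p.value
    })
    pairwise <- data.frame(
      design_a = colnames(m)[combs[1, ]],
      design_b = colnames(m)[combs[2, ]],
      p_raw = p_raw,
      p_bonferroni = pmin(p_raw * ncol(combs), 1))
  }
  normality <- vapply(seq_len(ncol(m)), function(j) {
    if (sd(m[, j]) == 0) return(NA_real_)
    tryCatch(nortest::lillie.test(m[, j])$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  names(normality) <- colnames(m)
  structure(list(friedman = list(chi_squared = unname(fr$statistic),
                                 df = unname(fr$parameter),
                                 p = fr$p.value),
                 pairwise = pairwise, normality = normality,
                 alpha = alpha),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("<design_comparison> Friedman chi-squared = ",
      signif(x$friedman$chi_squared, 4), " (df ", x$friedman$df,
      "), p = ", signif(x$friedman$p, 4), "\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("Bonferroni-corrected Wilcoxon signed-rank:\n")
    print(x$pairwise)
  } else {
    cat("Friedman not significant at alpha = ", x$alpha,
        "; no post-hoc tests\n", sep = "")
  }
  invisible(x)
}

#' Consumer-device montage presets
#'
#' Approximate channel sets mimicking common consumer EEG headsets, mapped
#' onto the default 32-channel montage for comparison runs. The exact
#' commercial layouts differ (some use sites absent from this montage);
#' these presets are best-effort stand-ins and are configurable.
#'
#' @param montage the montage the presets are validated against.
#' @return Named list of [channel_set()] objects.
#' @export
device_presets <- function(montage = default_montage()) {
  list(
    focusband2 = channel_set(c("Fp1", "Fp2"), montage),
    insight5 = channel_set(c("AF3", "AF4", "T7", "T8", "Pz"), montage),
    dsi7 = channel_set(c("F3", "F4", "C3", "C4", "P3", "P4", "Pz"),
                       montage),
    balert9 = channel_set(c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3",
                            "Pz", "P4"), montage))
}
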