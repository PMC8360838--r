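#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC is computed as the Mann-Whitney probability that a random positive
#' scores above a random negative, with ties counted half (rank formula).
#' The 95% confidence interval is a percentile bootstrap over records.
#'
#' @param scores Numeric scores (higher = more FaST-like).
#' @param labels Binary labels (0/1 or logical).
#' @param ci Compute the bootstrap interval?
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return A one-row tibble: `auc`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci = FALSE, n_boot = 2000,
                    conf = 0.95, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("`labels` must contain both classes.")
  }
  point <- auc_rank(scores, labels)
  lo <- hi <- NA_real_
  if (ci) {
    n <- length(scores)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) < 2) return(NA_real_)
        auc_rank(scores[idx], labels[idx])
      }, numeric(1))
    })
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(auc = point, ci_lower = lo, ci_upper = hi,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

# Mann-Whitney AUC via midranks: ties counted half.
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score threshold attaining a prespecified sensitivity
#'
#' Returns the largest threshold whose achieved sensitivity (under the
#' `score >= threshold` positive rule) is at least `target`. With `target =
#' 1` this is the minimum positive score.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param target Target sensitivity in (0, 1].
#' @return Numeric threshold.
#' @export
threshold_at_sensitivity <- function(scores, labels, target) {
  labels <- as.integer(as.logical(labels))
  stopifnot(target > 0, target <= 1)
  pos <- scores[labels == 1]
  if (length(pos) == 0) abort("No positive labels.")
  cand <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cand, function(th) mean(pos >= th), numeric(1))
  cand[which(sens >= target)[1]]
}

#' Operating-point metrics at a threshold
#'
#' Confusion-matrix rates at the `score >= threshold` rule. The report
#' satisfies the exact identities F1 = 2 PPV Se / (PPV + Se) and
#' accuracy = prevalence * Se + (1 - prevalence) * Sp.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `f1`, `accuracy`, `prevalence`, `tp`, `fp`, `tn`, `fn`.
#' @export
metrics_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) == 0) abort("Empty input.")
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- f1_score(ppv, se)
  tibble::tibble(
    threshold = threshold, sensitivity = se, specificity = sp,
    ppv = ppv, npv = npv, f1 = f1,
    accuracy = (tp + tn) / length(labels),
    prevalence = (tp + fn) / length(labels),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' F1 score as the harmonic mean of PPV and sensitivity
#'
#' @param ppv Positive predictive value.
#' @param sensitivity Sensitivity (recall).
#' @return Numeric F1 in \[0, 1\] (0 when both inputs are 0).
#' @export
f1_score <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity)) return(NA_real_)
  if (ppv + sensitivity == 0) return(0)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Accuracy from prevalence, sensitivity and specificity
#'
#' The exact identity accuracy = prevalence * Se + (1 - prevalence) * Sp,
#' used to cross-check reported operating-point tables.
#'
#' @param prevalence Positive-class prevalence.
#' @param sensitivity,specificity Operating-point rates.
#' @return Numeric accuracy.
#' @export
accuracy_identity <- function(prevalence, sensitivity, specificity) {
  prevalence * sensitivity + (1 - prevalence) * specificity
}

#' Operating points at prespecified sensitivities
#'
#' Evaluates [metrics_at_threshold()] at the thresholds attaining each target
#' sensitivity (the clinical operating points 85/90/95%, by default).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param sensitivities Target sensitivities.
#' @return Tibble with one row per target, including `target_sensitivity`.
#' @export
operating_points <- function(scores, labels,
                             sensitivities = c(0.85, 0.90, 0.95)) {
  rows <- lapply(sensitivities, function(s) {
    th <- threshold_at_sensitivity(scores, labels, s)
    dplyr::bind_cols(tibble::tibble(target_sensitivity = s),
                     metrics_at_threshold(scores, labels, th))
  })
  dplyr::bind_rows(rows)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement, with expected agreement from the product of
#' the marginals. When both raters are constant and identical (expected
#' agreement 1), kappa is defined as 1.
#'
#' @param labels_a,labels_b Equal-length binary label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.")
  }
  a <- as.integer(as.logical(labels_a))
  b <- as.integer(as.logical(labels_b))
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  if (pe == 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' Patient-level cross-validation plan
#'
#' @param n_folds Number of folds (patients are partitioned).
#' @param n_seeds Number of repeats; each seed draws a different partition.
#' @param subsample_fractions Optional fractions of training patients for a
#'   training-size curve.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 3, n_seeds = 5, subsample_fractions = NULL) {
  stopifnot(n_folds >= 2, n_seeds >= 1)
  structure(list(n_folds = n_folds, n_seeds = n_seeds,
                 subsample_fractions = subsample_fractions),
            class = "cv_plan")
}

#' Assign patients to folds
#'
#' @param patient_ids Character vector (one entry per record).
#' @param n_folds Number of folds.
#' @param seed Seed controlling the random partition.
#' @return Integer fold id per record; patients never straddle folds.
#' @export
patient_folds <- function(patient_ids, n_folds, seed = 1L) {
  patients <- unique(patient_ids)
  if (length(patients) < n_folds) {
    abort("Fewer patients than folds.")
  }
  with_seed(seed, {
    shuffled <- sample(patients)
    fold_of <- setNames(rep(seq_len(n_folds), length.out = length(shuffled)),
                        shuffled)
    unname(fold_of[patient_ids])
  })
}

#' Repeated patient-level cross-validation
#'
#' Runs `fit(x_train, y_train, seed)` / `score(fit, x_test)` over a
#' patient-level k-fold partition, repeated with `plan$n_seeds` seeds (each
#' seed draws a fresh partition and is passed to `fit` so that model
#' initialization also varies). Optional `subsample_fractions` refit on
#' nested subsets of the training patients for a training-size curve.
#'
#' @param x Numeric matrix, one row per record.
#' @param y Binary labels.
#' @param patient_ids Patient id per record.
#' @param plan A [cv_plan()].
#' @param fit Function `(x, y, seed) -> model`.
#' @param score Function `(model, x) -> numeric scores`.
#' @param seed Base seed; per-repeat seeds are derived from it.
#' @return A list of class `cv_result`: `folds` (tibble with one row per
#'   seed x fold x fraction: `seed`, `fold`, `fraction`, `auc`, `n_test`) and
#'   `summary` (mean and sd of AUC per fraction).
#' @export
cross_validate <- function(x, y, patient_ids, plan = cv_plan(),
                           fit, score, seed = 1L) {
  y <- as.integer(as.logical(y))
  fractions <- plan$subsample_fractions %||% 1
  seeds <- seed + seq_len(plan$n_seeds) - 1L

  rows <- list()
  for (s in seeds) {
    fold_id <- patient_folds(patient_ids, plan$n_folds, seed = s)
    for (f in seq_len(plan$n_folds)) {
      te <- fold_id == f
      tr_pat <- unique(patient_ids[!te])
      for (frac in fractions) {
        keep_pat <- with_seed(s + 1000L * f, {
          sample(tr_pat, max(1L, round(frac * length(tr_pat))))
        })
        tr <- !te & patient_ids %in% keep_pat
        if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
        model <- fit(x[tr, , drop = FALSE], y[tr], s)
        sc <- score(model, x[te, , drop = FALSE])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          seed = s, fold = f, fraction = frac,
          auc = roc_auc(sc, y[te])$auc, n_test = sum(te))
      }
    }
  }
  folds <- dplyr::bind_rows(rows)
  summary <- folds |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
                     n = dplyr::n(), .groups = "drop")
  structure(list(folds = folds, summary = summary, plan = plan),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  print(x$summary)
  invisible(x)
}
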