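#' Evaluation metrics from confusion counts
#'
#' Computes precision, recall, balanced F-score, accuracy and the Matthews
#' correlation coefficient from the four confusion counts, with the standard
#' zero-denominator guards (a ratio with zero denominator is reported as 0).
#'
#' @param tp,fp,fn,tn confusion counts (positive class = interaction).
#' @return named list: tp, fp, fn, tn, precision, recall, f_score,
#'   accuracy, mcc (all proportions in `[0, 1]`, mcc in `[-1, 1]`).
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  n <- tp + fp + fn + tn
  accuracy <- if (n > 0) (tp + tn) / n else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f_score = f_score,
       accuracy = accuracy, mcc = mcc)
}

#' Area under the ROC curve by the rank statistic
#'
#' The probability that a uniformly drawn positive instance receives a
#' higher decision value than a uniformly drawn negative one, ties counting
#' one half (equivalent to the Wilcoxon/Mann-Whitney statistic). Computed
#' from raw decision values, not probabilities.
#'
#' @param decisions numeric decision values.
#' @param gold logical gold labels.
#' @return AUC in `[0, 1]`; `NA` if one class is absent.
#' @export
auc_score <- function(decisions, gold) {
  gold <- as.logical(gold)
  n_pos <- sum(gold)
  n_neg <- sum(!gold)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(decisions, ties.method = "average")
  (sum(r[gold]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate decision values against gold labels
#'
#' Thresholds the decision values at `threshold` (positive decision =
#' predicted interaction) and reports the full metric set including the
#' rank-statistic AUC.
#'
#' @param decisions numeric decision values.
#' @param gold logical gold labels.
#' @param threshold decision threshold, default 0.
#' @return object of class `hsp_eval`: the [metrics_from_counts()] list
#'   plus `auc` and `n`.
#' @export
evaluate_predictions <- function(decisions, gold, threshold = 0) {
  if (!length(decisions)) stop("empty input")
  if (length(decisions) != length(gold)) {
    stop("decisions and gold labels must have equal length")
  }
  gold <- as.logical(gold)
  pred <- decisions > threshold
  m <- metrics_from_counts(
    tp = sum(pred & gold), fp = sum(pred & !gold),
    fn = sum(!pred & gold), tn = sum(!pred & !gold)
  )
  m$auc <- auc_score(decisions, gold)
  m$n <- length(decisions)
  class(m) <- "hsp_eval"
  m
}

#' @export
print.hsp_eval <- function(x, ...) {
  cat("evaluation (positive class = interaction)\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  cat(sprintf(
    "  P %.1f%%  R %.1f%%  F %.1f%%  Acc %.1f%%  MCC %.1f%%  AUC %s\n",
    100 * x$precision, 100 * x$recall, 100 * x$f_score, 100 * x$accuracy,
    100 * x$mcc,
    if (is.na(x$auc)) "NA" else sprintf("%.1f%%", 100 * x$auc)))
  if (!is.null(x$folds)) {
    cat(sprintf("  %d folds: sd(F) = %.3f, sd(AUC) = %.3f\n",
                nrow(x$folds), x$sigma_f, x$sigma_auc))
  }
  invisible(x)
}

#' Deterministic document-level fold assignment
#'
#' Documents (not instances) are partitioned into k folds so no sentence of
#' one document ends up in two folds, preventing same-sentence leakage.
#' Documents are shuffled by the seed, then dealt round-robin; identical
#' seed and document set yield identical folds regardless of instance order.
#'
#' @param doc_ids character vector, one per instance.
#' @param k number of folds.
#' @param seed RNG seed for the document shuffle.
#' @return integer fold assignment (1..k) per instance.
#' @export
assign_folds <- function(doc_ids, k, seed = 1L) {
  docs <- sort(unique(doc_ids))
  if (length(docs) < k) {
    stop(sprintf("fewer documents (%d) than folds (%d)", length(docs), k))
  }
  set.seed(seed)
  shuffled <- sample(docs)
  fold_of_doc <- stats::setNames(rep_len(seq_len(k), length(docs)), shuffled)
  unname(fold_of_doc[doc_ids])
}

#' Cross-validated evaluation on a precomputed Gram matrix
#'
#' Splits instances into document-disjoint folds, trains the maximum-margin
#' classifier on each training portion of the precomputed kernel matrix and
#' pools the held-out decisions. Reports pooled (micro) confusion metrics,
#' macro-averaged F, per-fold breakdown and the per-fold standard deviations
#' of F and AUC.
#'
#' @param K Gram matrix over all instances.
#' @param labels logical labels.
#' @param doc_ids document id per instance (fold unit).
#' @param k number of folds (default 10).
#' @param C SVM box constraint.
#' @param seed fold-assignment seed.
#' @return `hsp_eval` with extra fields `folds` (data.frame), `sigma_f`,
#'   `sigma_auc`, `macro_f`, `decisions`, `fold_assignment`.
#' @export
cross_validate <- function(K, labels, doc_ids, k = 10L, C = 1.0, seed = 1L) {
  n <- nrow(K)
  stopifnot(length(labels) == n, length(doc_ids) == n, k >= 2L)
  labels <- as.logical(labels)
  folds <- assign_folds(doc_ids, k, seed)
  decisions <- rep(NA_real_, n)
  fold_rows <- list()
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    if (!length(test)) next
    if (length(unique(labels[train])) < 2L) {
      stop(sprintf("fold %d: training portion has a single class", f))
    }
    model <- svm_train(K[train, train, drop = FALSE], labels[train], C = C)
    decisions[test] <- svm_decision(model, K[test, train, drop = FALSE])
    ev <- evaluate_predictions(decisions[test], labels[test])
    fold_rows[[f]] <- data.frame(
      fold = f, n = length(test), f_score = ev$f_score,
      auc = ev$auc, precision = ev$precision, recall = ev$recall
    )
  }
  pooled <- evaluate_predictions(decisions, labels)
  fold_df <- do.call(rbind, fold_rows)
  pooled$folds <- fold_df
  pooled$sigma_f <- stats::sd(fold_df$f_score)
  pooled$sigma_auc <- stats::sd(fold_df$auc, na.rm = TRUE)
  pooled$macro_f <- mean(fold_df$f_score)
  pooled$decisions <- decisions
  pooled$fold_assignment <- folds
  pooled
}
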