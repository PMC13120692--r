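# Protein-centric and term-centric evaluation.
#
# Fmax follows the CAFA convention: thresholds swept on a 0.01 grid,
# precision averaged over proteins that make at least one call at the
# threshold, recall averaged over proteins with at least one true term.
# AUPR uses step-wise (all-threshold) interpolation; ROC AUC uses the
# rank-sum (Mann-Whitney) formulation with half credit for ties.

#' Protein-centric Fmax
#'
#' Sweeps decision thresholds over `{0.01, 0.02, ..., 1.00}`. At each
#' threshold, precision is the mean over proteins with >= 1 predicted term
#' of TP / #calls, and recall is the mean over proteins with >= 1 true term
#' of TP / #true. Fmax is the maximum harmonic mean; ties resolve to the
#' smallest threshold. If no protein makes a call at any threshold the
#' precision is everywhere undefined and Fmax is 0 by convention.
#'
#' @param preds Protein x term probability matrix.
#' @param truth Binary matrix of the same shape (true-path-propagated).
#' @param thresholds Threshold grid.
#' @return List with `fmax` and `threshold`.
#' @export
fmax <- function(preds, truth, thresholds = seq(0.01, 1, by = 0.01)) {
  check_pred_truth(preds, truth)
  has_true <- rowSums(truth) > 0
  if (!any(has_true)) {
    stop_hiergo("no protein has a true term; Fmax undefined",
                class = "hiergo_validation_error")
  }
  best <- 0
  best_tau <- thresholds[1]
  for (tau in thresholds) {
    calls <- preds >= tau
    n_calls <- rowSums(calls)
    tp <- rowSums(calls & (truth > 0))
    covered <- n_calls > 0
    if (!any(covered)) next
    prec <- mean(tp[covered] / n_calls[covered])
    rec <- mean(tp[has_true] / rowSums(truth)[has_true])
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f > best + 1e-12) {
      best <- f
      best_tau <- tau
    }
  }
  list(fmax = best, threshold = best_tau)
}

#' @noRd
check_pred_truth <- function(preds, truth) {
  if (!is.matrix(preds) || !is.matrix(truth) ||
      !all(dim(preds) == dim(truth))) {
    stop_hiergo("predictions and truth must be matrices of equal shape",
                class = "hiergo_validation_error")
  }
  if (any(preds < 0 | preds > 1)) {
    stop_hiergo("prediction entries must lie in [0, 1]",
                class = "hiergo_validation_error")
  }
  invisible(TRUE)
}

# Step-wise-interpolated area under the precision-recall curve for one
# score vector: sum over distinct descending thresholds of
# precision * (recall step).
#' @noRd
aupr_single <- function(scores, labels) {
  n_pos <- sum(labels > 0)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord] > 0
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Macro-averaged AUPR
#'
#' Mean over terms of per-term area under the precision-recall curve.
#' Terms without a single positive are excluded (and reported).
#'
#' @param preds Protein x term probability matrix.
#' @param truth Matching binary matrix.
#' @return List with `aupr`, `n_terms` scored and `excluded` term columns.
#' @export
macro_aupr <- function(preds, truth) {
  check_pred_truth(preds, truth)
  per_term <- vapply(seq_len(ncol(preds)), function(j) {
    aupr_single(preds[, j], truth[, j])
  }, 0)
  if (all(is.na(per_term))) {
    stop_hiergo("no term has a positive example",
                class = "hiergo_validation_error")
  }
  list(aupr = mean(per_term, na.rm = TRUE),
       n_terms = sum(!is.na(per_term)),
       excluded = which(is.na(per_term)))
}

#' Micro-averaged AUPR
#'
#' AUPR over the flattened protein-term pairs.
#'
#' @inheritParams macro_aupr
#' @return Scalar AUPR.
#' @export
micro_aupr <- function(preds, truth) {
  check_pred_truth(preds, truth)
  out <- aupr_single(as.vector(preds), as.vector(truth))
  if (is.na(out)) {
    stop_hiergo("no positive example anywhere",
                class = "hiergo_validation_error")
  }
  out
}

#' ROC AUC by rank statistic (ties get half credit)
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (>0 = positive).
#' @return AUC in [0, 1], or NA if one class is absent.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-term ROC AUC table
#'
#' Terms lacking either a positive or a negative example are excluded from
#' scoring and flagged in the output.
#'
#' @param preds Protein x term probability matrix (column names = term ids
#'   if available).
#' @param truth Matching binary matrix.
#' @param term_ids Optional term ids per column.
#' @return Data frame with `term_id`, `auc`, `n_pos`, `n_neg`.
#' @export
per_term_auc <- function(preds, truth, term_ids = colnames(preds)) {
  check_pred_truth(preds, truth)
  if (is.null(term_ids)) term_ids <- as.character(seq_len(ncol(preds)))
  data.frame(
    term_id = term_ids,
    auc = vapply(seq_len(ncol(preds)), function(j) {
      roc_auc(preds[, j], truth[, j])
    }, 0),
    n_pos = colSums(truth > 0),
    n_neg = colSums(truth == 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Term-centric AUC
#'
#' Unweighted mean of per-term ROC AUCs over terms with both classes
#' present (the macro-averaged reading of a term-centric "AUC" column).
#'
#' @inheritParams per_term_auc
#' @return Scalar AUC.
#' @export
term_centric_auc <- function(preds, truth) {
  tab <- per_term_auc(preds, truth)
  mean(tab$auc, na.rm = TRUE)
}

#' Full evaluation report
#'
#' @param preds Protein x term probability matrix (columns named by term).
#' @param truth Matching binary matrix.
#' @param exclude_roots Term ids to exclude from scoring (aspect roots are
#'   always-true after propagation and are excluded by default upstream).
#' @return Object of class `eval_report`: `fmax`, `threshold`,
#'   `macro_aupr`, `micro_aupr`, `auc` (term-centric), `per_term` table.
#' @export
evaluate_predictions <- function(preds, truth, exclude_roots = NULL) {
  if (!is.null(exclude_roots) && !is.null(colnames(preds))) {
    keep <- !(colnames(preds) %in% exclude_roots)
    preds <- preds[, keep, drop = FALSE]
    truth <- truth[, keep, drop = FALSE]
  }
  fm <- fmax(preds, truth)
  structure(list(
    fmax = fm$fmax, threshold = fm$threshold,
    macro_aupr = macro_aupr(preds, truth)$aupr,
    micro_aupr = micro_aupr(preds, truth),
    auc = term_centric_auc(preds, truth),
    per_term = per_term_auc(preds, truth)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: Fmax %.3f (tau = %.2f)  MacroAUPR %.3f  MicroAUPR %.3f  AUC %.3f\n",
    x$fmax, x$threshold, x$macro_aupr, x$micro_aupr, x$auc))
  invisible(x)
}
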