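# Performance measures: confusion matrix at the 0.5 score threshold,
# Matthews correlation coefficient with explicit undefined (NaN) handling,
# AU-ROC (rank form, equivalent to trapezoidal integration with
# tie-averaging), AU-PRC as average precision, and the paired Wilcoxon
# signed-rank comparison of two methods across dataset x fold cells.

#' Confusion counts at a score threshold
#'
#' A protein is called a TF when its score is strictly greater than the
#' threshold, and non-TF when the score is less than or equal to it (so a
#' score of exactly 0.5 is a non-TF call at the default threshold).
#'
#' @param labels Binary labels (0/1 or logical), 1 = TF.
#' @param scores Numeric scores of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_at_threshold <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(scores)) stop("length mismatch")
  pred <- scores > threshold
  c(tp = sum(pred & labels == 1L), fp = sum(pred & labels == 0L),
    tn = sum(!pred & labels == 0L), fn = sum(!pred & labels == 1L))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any of the
#' four marginal sums is zero (e.g. a model that predicts everything
#' negative) the coefficient is undefined and returned as `NaN`; aggregate
#' tables propagate it as missing rather than treating it as zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Real in `[-1, 1]`, or `NaN` when undefined.
#' @export
#' @examples
#' mcc(3, 1, 5, 1)  # 14/24
mcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(NaN)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Area under the ROC curve
#'
#' Computed in rank form: the fraction of (TF, non-TF) pairs in which the
#' TF receives the higher score, counting ties as one half. This equals
#' trapezoidal integration of the ROC curve with tied scores grouped.
#'
#' @param labels Binary labels (1 = TF); both classes must be present.
#' @param scores Numeric scores.
#' @return AU-ROC in `[0, 1]`.
#' @export
au_roc <- function(labels, scores) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average precision: the step-wise integral `sum (R_i - R_{i-1}) * P_i`
#' over score thresholds taken at each distinct score value (descending),
#' with tied scores entering as one group. This estimator avoids the
#' optimistic bias of linear interpolation between PR points.
#'
#' @inheritParams au_roc
#' @return AU-PRC in `(0, 1]`.
#' @export
au_prc <- function(labels, scores) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L || sum(!labels) == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- cumsum(lab)[grp_end]
  n_called <- grp_end
  precision <- tp / n_called
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a score vector
#'
#' Bundles the three study measures plus the confusion counts at the 0.5
#' threshold into one result row.
#'
#' @inheritParams confusion_at_threshold
#' @return Named list: `au_roc`, `au_prc`, `mcc` (possibly `NaN`), `tp`,
#'   `fp`, `tn`, `fn`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  cm <- confusion_at_threshold(labels, scores, threshold)
  labels <- as.logical(labels)
  list(au_roc = au_roc(labels, scores), au_prc = au_prc(labels, scores),
       mcc = mcc(cm["tp"], cm["fp"], cm["tn"], cm["fn"]),
       tp = unname(cm["tp"]), fp = unname(cm["fp"]),
       tn = unname(cm["tn"]), fn = unname(cm["fn"]),
       n_pos = sum(labels), n_neg = sum(!labels))
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired performance values (one pair per
#' dataset x test-fold cell). Zero differences are dropped; the exact null
#' distribution is used for 25 or fewer non-zero pairs without ties in the
#' absolute differences, otherwise the normal approximation. If every
#' difference is zero the methods are indistinguishable and p = 1.
#'
#' @param values_a,values_b Equal-length numeric vectors of paired
#'   performance values.
#' @return Two-sided p-value.
#' @export
paired_wilcoxon <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided",
                       exact = length(d) <= 25L && !any(duplicated(abs(d)))))
  unname(res$p.value)
}

#' Aggregate per-fold results into a mean +/- sd table
#'
#' Mirrors the study's summary layout: one row per method x dataset with
#' the mean and standard deviation of each measure over the test folds.
#' Undefined MCC values propagate as missing.
#'
#' @param results Data frame from [run_grid()].
#' @return Data frame with `mean_`/`sd_` columns for the three measures.
#' @export
aggregate_results <- function(results) {
  keys <- unique(results[, c("method", "dataset")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$method == keys$method[i] &
                     results$dataset == keys$dataset[i], ]
    stat <- function(x) c(mean = mean(x), sd = stats::sd(x))
    data.frame(method = keys$method[i], dataset = keys$dataset[i],
               n_folds = nrow(sub),
               mean_au_roc = mean(sub$au_roc), sd_au_roc = stats::sd(sub$au_roc),
               mean_au_prc = mean(sub$au_prc), sd_au_prc = stats::sd(sub$au_prc),
               mean_mcc = mean(sub$mcc), sd_mcc = stats::sd(sub$mcc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
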