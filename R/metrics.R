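## Confusion-count metrics, ROC/AUC by threshold sweep, fold confidence
## intervals (Student t) and paired fold tests.

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity, F1 and FPR from
#' TP/FP/TN/FN. Ratios with zero denominators are reported as `NA`
#' (explicit undefined markers), never silently 0.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return Named list of metrics plus the counts.
#' @export
fd_metrics <- function(tp, fp, tn, fn) {
  .fd_assert(all(c(tp, fp, tn, fn) >= 0), "counts must be nonnegative")
  total <- tp + fp + tn + fn
  .fd_assert(total > 0, "no evaluated items")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = div(tp + tn, total),
       precision = precision,
       recall = recall,
       specificity = div(tn, tn + fp),
       f1 = f1,
       fpr = div(fp, fp + tn))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a cutoff (`score >= cutoff` predicts
#' positive) and integrates the ROC curve by trapezoid, which equals the
#' rank statistic (probability that a random positive outscores a random
#' negative, ties counted 1/2).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (1/TRUE = positive).
#' @return List with `auc` and a `curve` data.frame (`fpr`, `tpr`,
#'   `threshold`).
#' @export
fd_roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  .fd_assert(length(scores) == length(labels), "length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  .fd_assert(np > 0 && nn > 0, "both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1) / np,
                numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0) / nn,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Fold-wise confidence interval (Student t)
#'
#' Two-sided interval `mean +/- t_{1-(1-conf)/2, n-1} * s / sqrt(n)` over
#' per-fold metric values; at the 16-fold default protocol the critical
#' value is t_{0.975,15} ~ 2.131.
#'
#' @param values Per-fold metric values (n >= 2).
#' @param conf Confidence level.
#' @return List with `mean`, `sd`, `n`, `t_crit`, `half_width`, `lower`,
#'   `upper`.
#' @export
fd_fold_ci <- function(values, conf = 0.95) {
  n <- length(values)
  .fd_assert(n >= 2, "need at least 2 folds")
  m <- mean(values); s <- stats::sd(values)
  tc <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  hw <- tc * s / sqrt(n)
  list(mean = m, sd = s, n = n, t_crit = tc, half_width = hw,
       lower = m - hw, upper = m + hw)
}

#' Paired two-sided t-test over folds
#'
#' Classic paired t on per-fold differences (df = n - 1). A zero-variance
#' difference vector is reported as an explicit degenerate result rather
#' than a p-value.
#'
#' @param a,b Per-fold metric values for the two methods (equal length
#'   >= 2).
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
fd_paired_t <- function(a, b) {
  .fd_assert(length(a) == length(b) && length(a) >= 2,
             "need two equal-length vectors with n >= 2")
  d <- a - b
  if (stats::sd(d) < 1e-15) {
    return(list(statistic = NA_real_, df = length(d) - 1,
                p_value = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}
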