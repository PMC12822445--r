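#' Area under the ROC curve via the rank statistic
#'
#' Mann-Whitney formulation with midrank tie correction: the probability
#' that a random positive outscores a random negative, ties counting 1/2.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUROC in \[0, 1\]; `NA` if a class is absent.
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)                        # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise interpolation: precision evaluated at every positive hit in
#' decreasing-score order, averaged over positives (ties processed in one
#' block using the block's trailing precision).
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]; `NA` if no positives.
#' @export
auprc <- function(scores, positive) {
  positive <- as.logical(positive)
  npos <- sum(positive)
  if (npos == 0L || npos == length(positive)) {
    if (npos == length(positive)) return(1)
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  y <- positive[o]; s <- scores[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  # collapse score ties: every member of a tied block sees the precision at
  # the end of the block
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  block_prec <- prec
  idx <- which(last_of_block)
  block_prec <- rep(prec[idx], times = diff(c(0L, idx)))
  sum(block_prec[y]) / npos
}

#' Spearman rank correlation with p-value
#'
#' Exact p for n <= 10 without ties, t-distribution approximation
#' otherwise (the standard large-sample treatment).
#'
#' @param x,y numeric vectors.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 10L && !anyDuplicated(x) &&
                             !anyDuplicated(y))))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Full metric report over bag predictions
#'
#' Risk groups are derived from the normalized labels (<= 0.5 high,
#' > 0.5 low). Reported: AUROC (low-risk as positive, score = prediction),
#' balanced accuracy at the 0.5 prediction threshold, AUPRC in both
#' polarities (low-as-positive scores the prediction, high-as-positive
#' scores `1 - prediction`), threshold-0.5 precision/recall/F1 in macro
#' and support-weighted form, and the Spearman correlation of the
#' continuous pairs. With single-class labels the classification metrics
#' are `NA` and the correlation is still computed.
#'
#' @param predictions numeric predictions in \[0, 1\].
#' @param labels_normalized numeric labels in \[0, 1\].
#' @return list of class `metric_report`.
#' @export
compute_metrics <- function(predictions, labels_normalized) {
  if (length(predictions) != length(labels_normalized))
    stop_invalid("predictions and labels must have equal length")
  if (length(predictions) < 2L)
    stop_invalid("at least two cases are required")
  grp <- assign_risk_group(labels_normalized, "normalized")
  pred_grp <- assign_risk_group(pmin(pmax(predictions, 0), 1), "normalized")
  is_low <- grp == "low"
  both <- length(unique(grp)) == 2L

  if (both) {
    auc <- auroc(predictions, is_low)
    rec_low <- mean(pred_grp[is_low] == "low")
    rec_high <- mean(pred_grp[!is_low] == "high")
    bacc <- (rec_low + rec_high) / 2
    ap_low <- auprc(predictions, is_low)
    ap_high <- auprc(1 - predictions, !is_low)
    prf <- function(cls) {
      tp <- sum(pred_grp == cls & grp == cls)
      prec <- if (sum(pred_grp == cls)) tp / sum(pred_grp == cls) else 0
      rec <- tp / sum(grp == cls)
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(prec, rec, f1, sum(grp == cls))
    }
    m <- rbind(low = prf("low"), high = prf("high"))
    w <- m[, 4L] / sum(m[, 4L])
    macro <- colMeans(m[, 1:3])
    wavg <- colSums(m[, 1:3] * w)
  } else {
    auc <- bacc <- ap_low <- ap_high <- NA_real_
    macro <- wavg <- rep(NA_real_, 3L)
  }
  sp <- spearman(predictions, labels_normalized)
  structure(list(
    auroc = auc, balanced_accuracy = bacc,
    auprc_low_positive = ap_low, auprc_high_positive = ap_high,
    precision_macro = macro[1], recall_macro = macro[2], f1_macro = macro[3],
    precision_weighted = wavg[1], recall_weighted = wavg[2],
    f1_weighted = wavg[3],
    spearman_r = sp$rho, spearman_p = sp$p,
    n = length(predictions)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d\n  AUROC %.3f | bACC %.3f | AUPRC low %.3f / high %.3f\n  Spearman R %.3f (p %.3g)\n",
    x$n, x$auroc, x$balanced_accuracy, x$auprc_low_positive,
    x$auprc_high_positive, x$spearman_r, x$spearman_p))
  invisible(x)
}
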