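#' Empirical ROC curve
#'
#' True positive rate against false positive rate under the decision rule
#' "predict positive when score >= threshold", with the threshold swept over
#' every distinct score. Tied scores collapse to a single vertex, so a tie
#' group appears as a diagonal chord and the trapezoidal area under the
#' curve equals the tie-aware rank (Mann-Whitney) AUC exactly.
#'
#' @param scores a [labeled_scores()] object with both classes present.
#' @return data frame of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`; the first row is the (0,0) point at threshold +Inf and the last
#'   row is (1,1) at the minimum score.
#' @examples
#' roc_curve(labeled_scores(c(3, 2, 1), c(1, 1, 0)))
#' @export
roc_curve <- function(scores) {
  .check_both_classes(scores)
  o <- order(scores$score, decreasing = TRUE)
  s <- scores$score[o]
  y <- scores$label[o]
  n1 <- sum(y)
  n0 <- length(y) - n1
  grp <- rle(s)
  ends <- cumsum(grp$lengths)
  tp <- cumsum(y)[ends]
  fp <- ends - tp
  structure(
    data.frame(
      threshold = c(Inf, grp$values),
      fpr = c(0, fp / n0),
      tpr = c(0, tp / n1)
    ),
    class = c("roc_curve", "data.frame"),
    n_pos = n1, n_neg = n0
  )
}

#' Area under the ROC curve, tie-aware
#'
#' Probability that a random positive item outscores a random negative item,
#' with half credit for ties, estimated by the rank (Mann-Whitney) statistic.
#' Identical to the trapezoidal area under [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc <- function(scores) {
  .check_both_classes(scores)
  y <- scores$label
  r <- rank(scores$score) # mid-ranks on ties
  n1 <- as.numeric(sum(y))
  n0 <- length(y) - n1
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Truncated, normalized AUC over the low-FPR region
#'
#' Trapezoidal area under the ROC curve restricted to FPR in `[0, fpr_cap]`,
#' with the curve linearly interpolated at the cap, divided by `fpr_cap`
#' (the maximum achievable area in that strip). Emphasizes the clinically
#' relevant low-false-positive regime; the chance level is `fpr_cap / 2`.
#'
#' @inheritParams roc_curve
#' @param fpr_cap upper FPR bound, in (0, 1]; default 0.2.
#' @return normalized truncated AUC in [0, 1].
#' @export
truncated_auc <- function(scores, fpr_cap = 0.2) {
  stopifnot(fpr_cap > 0, fpr_cap <= 1)
  rc <- roc_curve(scores)
  f <- rc$fpr
  t <- rc$tpr
  i <- max(which(f <= fpr_cap))
  f2 <- f[seq_len(i)]
  t2 <- t[seq_len(i)]
  if (f[i] < fpr_cap) { # interpolate on the chord to the next vertex
    j <- i + 1L
    t_cap <- t[i] + (t[j] - t[i]) * (fpr_cap - f[i]) / (f[j] - f[i])
    f2 <- c(f2, fpr_cap)
    t2 <- c(t2, t_cap)
  }
  k <- length(f2)
  area <- sum(diff(f2) * (t2[-k] + t2[-1L]) / 2)
  area / fpr_cap
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Applies the rule "score >= tau is a positive prediction" and reports the
#' four rates, Matthews correlation coefficient, and the global likelihood
#' ratios LR+ = TPR/FPR, LR- = (1-TPR)/(1-FPR) and diagnostic odds ratio
#' DOR = LR+/LR-. Divisions by zero yield +Inf (or NaN for 0/0) and set the
#' `degenerate` flag rather than erroring; a degenerate MCC (empty row or
#' column of the confusion matrix) is reported as 0 with a warning.
#'
#' @inheritParams roc_curve
#' @param tau decision threshold on the (orientation-normalized) score.
#' @return list of class `threshold_metrics`: `tp`, `fp`, `fn`, `tn`, `tpr`,
#'   `fpr`, `tnr`, `fnr`, `mcc`, `lr_plus`, `lr_minus`, `dor`, `degenerate`.
#' @export
threshold_metrics <- function(scores, tau) {
  .check_both_classes(scores)
  pred <- scores$score >= tau
  y <- scores$label == 1
  tp <- sum(pred & y)
  fp <- sum(pred & !y)
  fn <- sum(!pred & y)
  tn <- sum(!pred & !y)
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (mcc_den == 0) {
    warning("degenerate confusion matrix; MCC reported as 0", call. = FALSE)
    mcc <- 0
  } else {
    mcc <- (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  }
  lr_plus <- if (fpr > 0) tpr / fpr else if (tpr > 0) Inf else NaN
  lr_minus <- if (fpr < 1) (1 - tpr) / (1 - fpr) else if (tpr < 1) Inf else NaN
  dor <- if (is.nan(lr_plus) || is.nan(lr_minus)) {
    NaN
  } else if (lr_minus == 0) {
    if (lr_plus > 0) Inf else NaN
  } else {
    lr_plus / lr_minus
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         tpr = tpr, fpr = fpr, tnr = 1 - fpr, fnr = 1 - tpr,
         mcc = mcc, lr_plus = lr_plus, lr_minus = lr_minus, dor = dor,
         degenerate = fpr == 0 || fpr == 1 || tpr == 0 || tpr == 1),
    class = "threshold_metrics"
  )
}

#' @export
print.threshold_metrics <- function(x, ...) {
  cat(sprintf("<threshold_metrics> TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  TPR=%.4f FPR=%.4f MCC=%.4f LR+=%.4g LR-=%.4g DOR=%.4g\n",
              x$tpr, x$fpr, x$mcc, x$lr_plus, x$lr_minus, x$dor))
  invisible(x)
}

# Empirical TPR/FPR at each threshold in `tau` (vectorized; rule: score >= tau).
.rates_at <- function(scores, tau) {
  sp <- sort(scores$score[scores$label == 1])
  sn <- sort(scores$score[scores$label == 0])
  tpr <- 1 - findInterval(tau, sp, left.open = TRUE) / length(sp)
  fpr <- 1 - findInterval(tau, sn, left.open = TRUE) / length(sn)
  list(tpr = tpr, fpr = fpr)
}

#' Write ROC points to a TSV file
#'
#' Columns `threshold`, `fpr`, `tpr`, one row per ROC vertex, for external
#' plotting.
#'
#' @param roc a [roc_curve()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.table(as.data.frame(roc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
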