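# Phase-1 evaluation: ROC/AUC with DeLong inference, threshold metrics with
# Wilson intervals, and calibration tables.

# Midrank placements: for each positive score, the fraction of negatives it
# exceeds (ties count 1/2), and vice versa. These are DeLong's structural
# components and also give O(n log n) leave-one-out AUCs.
auc_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v_pos <- (r_all[seq_len(n1)] - r_pos) / n0
  v_neg <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  # rank-sum form: sums of midranks are exact in binary, so this equals
  # brute-force pairwise concordance bit for bit
  auc <- (sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, v_pos = v_pos, v_neg = v_neg, n1 = n1, n0 = n0)
}

#' Empirical AUC with DeLong variance and confidence interval
#'
#' AUC is the Mann-Whitney statistic with half credit for ties. The variance
#' is DeLong's structural-components estimator
#' `var(V10)/n1 + var(V01)/n0`; the 95% CI is `auc +/- z * sqrt(var)`,
#' clipped to `[0, 1]`.
#'
#' @param scores Numeric prediction scores (ties allowed).
#' @param labels Binary labels (0/1).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `roc_result`: `auc`, `variance`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc_delong <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pl <- auc_placements(scores, labels)
  variance <- stats::var(pl$v_pos) / pl$n1 + stats::var(pl$v_neg) / pl$n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = pl$auc, variance = variance,
                 ci_low = max(0, pl$auc - z * sqrt(variance)),
                 ci_high = min(1, pl$auc + z * sqrt(variance)),
                 n_pos = pl$n1, n_neg = pl$n0),
            class = "roc_result")
}

#' Threshold classification metrics with Wilson intervals
#'
#' Standard 2x2 definitions of sensitivity, specificity, PPV, and NPV, each
#' with a Wilson score 95% CI. A metric with a zero denominator is returned
#' as `NA` and flagged rather than raising an error.
#'
#' @param predictions Binary predictions (`"positive"`/`"negative"`, logical,
#'   or 0/1).
#' @param labels Binary labels (0/1).
#' @param conf_level Confidence level.
#' @return A data.frame with one row per metric: `estimate`, `ci_low`,
#'   `ci_high`, `numerator`, `denominator`, `undefined`.
#' @export
confusion_metrics <- function(predictions, labels, conf_level = 0.95) {
  if (is.character(predictions)) predictions <- predictions == "positive"
  pred <- as.logical(predictions)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  fp <- sum(pred & y == 0); tn <- sum(!pred & y == 0)
  metric <- function(name, num, den) {
    if (den == 0) {
      data.frame(metric = name, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, numerator = num, denominator = den,
                 undefined = TRUE)
    } else {
      ci <- wilson_ci(num, den, conf_level)
      data.frame(metric = name, estimate = num / den, ci_low = ci[["lower"]],
                 ci_high = ci[["upper"]], numerator = num, denominator = den,
                 undefined = FALSE)
    }
  }
  rbind(metric("sensitivity", tp, tp + fn),
        metric("specificity", tn, tn + fp),
        metric("ppv", tp, tp + fp),
        metric("npv", tn, tn + fn))
}

#' Calibration table over equal-width probability bins
#'
#' Predictions are binned into `n_bins` equal-width bins on `[0, 1]`; each
#' occupied bin reports the mean prediction, the observed event frequency,
#' the count, and a Wilson 95% CI of the observed frequency. Empty bins are
#' omitted.
#'
#' @param means Predicted probabilities.
#' @param labels Binary labels.
#' @param n_bins Number of bins (default 10).
#' @return A data.frame of class `calibration_table`.
#' @export
calibration_table <- function(means, labels, n_bins = 10L) {
  stop_if_not_prob(means, "means")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(means, edges, rightmost.closed = TRUE), n_bins)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    k <- sum(labels[sel]); n <- sum(sel)
    ci <- wilson_ci(k, n)
    data.frame(bin = b, bin_low = edges[b], bin_high = edges[b + 1],
               predicted_mean = mean(means[sel]), observed = k / n,
               count = n, ci_low = ci[["lower"]], ci_high = ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", class(out))
  out
}

#' Empirical ROC curve points
#'
#' @param scores Prediction scores.
#' @param labels Binary labels.
#' @return A data.frame of (`fpr`, `tpr`) points, from (0,0) to (1,1),
#'   computed at every distinct threshold (ties handled jointly).
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  keep <- c(diff(s) != 0, TRUE)   # last index of each tie block
  tpr <- cumsum(y == 1)[keep] / n1
  fpr <- cumsum(y == 0)[keep] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}
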