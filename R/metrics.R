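#' Sensitivity and specificity at a decision threshold
#'
#' The decision rule is: predict positive iff `score >= threshold`.
#' Sensitivity is TP/(TP+FN) over the positive images, specificity TN/(TN+FP)
#' over the negatives. Metrics are computed image-wise (one row, one image);
#' no case-level aggregation is performed.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels 0/1 labels, both classes present.
#' @param threshold Decision threshold in \[0, 1\].
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @examples
#' sen_spc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)
#' @export
sen_spc <- function(scores, labels, threshold) {
  assert_scores(scores, "scores")
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  pred <- scores >= threshold
  c(sensitivity = mean(pred[labels == 1]),
    specificity = mean(!pred[labels == 0]))
}

#' Image-wise area under the ROC curve
#'
#' Mann-Whitney concordance probability: the probability that a random
#' positive scores above a random negative, with ties counted 1/2. Computed
#' by the rank formula, which realises exactly that convention.
#'
#' @inheritParams sen_spc
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  assert_scores(scores, "scores")
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores) # average rank for ties -> ties count 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden's index at a threshold
#'
#' `J = sensitivity + specificity - 1`: a compound accuracy measure of the
#' operating point, equal to `2 * balanced accuracy - 1`.
#'
#' @inheritParams sen_spc
#' @return J in \[-1, 1\].
#' @export
youden_index <- function(scores, labels, threshold) {
  ss <- sen_spc(scores, labels, threshold)
  unname(ss[1L] + ss[2L] - 1)
}

# All decision thresholds worth scanning: midpoints between adjacent distinct
# scores, plus the endpoints 0 and 1. Finite, exact and reproducible.
candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  mid <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else numeric(0)
  sort(unique(c(0, mid, 1)))
}

threshold_scan <- function(scores, labels, thresholds) {
  pos <- sort(scores[labels == 1])
  neg <- sort(scores[labels == 0])
  # findInterval(t, x, left.open = TRUE) counts x < t, so x >= t is n - that
  sens <- (length(pos) - findInterval(thresholds, pos, left.open = TRUE)) / length(pos)
  spec <- findInterval(thresholds, neg, left.open = TRUE) / length(neg)
  data.frame(threshold = thresholds, sensitivity = sens, specificity = spec)
}

#' Select the balanced operating point
#'
#' Chooses the decision threshold at which sensitivity equals specificity —
#' the balanced operating point used to pre-calibrate a screening classifier.
#' The scan is exact over all candidate thresholds (midpoints between
#' adjacent distinct scores plus 0 and 1); ties in `|SEN - SPC|` are broken
#' by the smallest threshold.
#'
#' @inheritParams sen_spc
#' @return An `operating_point`: list with `threshold`, `rule = "balanced"`,
#'   `sensitivity`, `specificity`, `gap` (achieved `|SEN - SPC|`) and a
#'   `provenance` string recording the data it was derived from.
#' @export
select_threshold_balanced <- function(scores, labels) {
  assert_scores(scores, "scores")
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  scan <- threshold_scan(scores, labels, candidate_thresholds(scores))
  gap <- abs(scan$sensitivity - scan$specificity)
  i <- which.min(gap) # first minimum = smallest threshold
  new_operating_point(
    threshold = scan$threshold[i], rule = "balanced", target_value = NA_real_,
    sensitivity = scan$sensitivity[i], specificity = scan$specificity[i],
    gap = gap[i],
    provenance = sprintf("balanced operating point on %d scores (%d+/%d-)",
                         length(scores), sum(labels == 1), sum(labels == 0))
  )
}

#' Select the threshold attaining a target specificity
#'
#' Smallest candidate threshold whose specificity is at least `target_spc`.
#' If no candidate below 1 attains the target (e.g. heavy ties at the top of
#' the score range), the degenerate threshold 1 is returned with
#' `degenerate = TRUE`.
#'
#' @inheritParams sen_spc
#' @param target_spc Target specificity in (0, 1).
#' @return An `operating_point` with `rule = "target_specificity"`.
#' @export
select_threshold_at_specificity <- function(scores, labels, target_spc) {
  assert_scores(scores, "scores")
  assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels),
            is.numeric(target_spc), length(target_spc) == 1L,
            target_spc > 0, target_spc < 1)
  scan <- threshold_scan(scores, labels, candidate_thresholds(scores))
  ok <- which(scan$specificity >= target_spc & scan$threshold < 1)
  degenerate <- length(ok) == 0L
  if (degenerate) {
    warning(sprintf("target specificity %.3f unreachable below threshold 1; returning the degenerate threshold",
                    target_spc), call. = FALSE)
    i <- nrow(scan)
  } else {
    i <- ok[1L]
  }
  new_operating_point(
    threshold = scan$threshold[i], rule = "target_specificity",
    target_value = target_spc,
    sensitivity = scan$sensitivity[i], specificity = scan$specificity[i],
    gap = abs(scan$sensitivity[i] - scan$specificity[i]),
    provenance = sprintf("target specificity %.3f on %d scores", target_spc,
                         length(scores)),
    degenerate = degenerate
  )
}

new_operating_point <- function(threshold, rule, target_value, sensitivity,
                                specificity, gap, provenance,
                                degenerate = FALSE) {
  structure(
    list(threshold = threshold, rule = rule, target_value = target_value,
         sensitivity = sensitivity, specificity = specificity, gap = gap,
         provenance = provenance, degenerate = degenerate),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> threshold %.6f (rule: %s)\n", x$threshold, x$rule))
  cat(sprintf("  at selection: SEN %.4f, SPC %.4f  |SEN-SPC| = %.4f\n",
              x$sensitivity, x$specificity, x$gap))
  if (isTRUE(x$degenerate)) cat("  WARNING: degenerate threshold\n")
  invisible(x)
}

#' Expected calibration error
#'
#' Scores are binned into `n_bins` equal-width bins of \[0, 1\]; the ECE is
#' the bin-size-weighted mean absolute gap between the mean score and the
#' observed positive fraction, `sum_b (n_b/N) |mean(score_b) - mean(label_b)|`.
#' Empty bins contribute nothing. Score 0 falls in the first bin; bin `b`
#' covers `((b-1)/n_bins, b/n_bins]`.
#'
#' @inheritParams sen_spc
#' @param n_bins Number of equal-width bins (default 10, the convention of
#'   the calibration literature).
#' @return ECE in \[0, 1\].
#' @export
expected_calibration_error <- function(scores, labels, n_bins = 10L) {
  assert_scores(scores, "scores")
  assert_binary_labels(labels, require_both = FALSE)
  stopifnot(length(scores) == length(labels))
  n_bins <- assert_count(n_bins, min = 1L)
  bin <- pmax(ceiling(scores * n_bins), 1L)
  gaps <- vapply(split(seq_along(scores), bin), function(idx) {
    length(idx) * abs(mean(scores[idx]) - mean(labels[idx]))
  }, numeric(1L))
  sum(gaps) / length(scores)
}

#' Full metrics report at an operating point
#'
#' Sensitivity, specificity, ROC-AUC, Youden's index and (when labels are
#' complete) the expected calibration error, at a fixed threshold.
#'
#' @inheritParams sen_spc
#' @param n_bins Bins for the ECE component.
#' @return A `metrics_report` list: `sensitivity`, `specificity`, `auc`,
#'   `youden`, `ece`, `n_pos`, `n_neg`, `threshold`.
#' @export
metrics_report <- function(scores, labels, threshold, n_bins = 10L) {
  ss <- sen_spc(scores, labels, threshold)
  structure(
    list(sensitivity = unname(ss[1L]), specificity = unname(ss[2L]),
         auc = roc_auc(scores, labels),
         youden = unname(ss[1L] + ss[2L] - 1),
         ece = expected_calibration_error(scores, labels, n_bins),
         n_pos = sum(labels == 1), n_neg = sum(labels == 0),
         threshold = threshold),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> at threshold %.6f (%d+/%d-)\n",
              x$threshold, x$n_pos, x$n_neg))
  cat(sprintf("  SEN %.4f  SPC %.4f  AUC %.4f  Youden %.4f  ECE %.4f\n",
              x$sensitivity, x$specificity, x$auc, x$youden, x$ece))
  invisible(x)
}

# Streaming-safe variant: returns NA rather than erroring when a class is
# absent in a small weekly slice.
gap_metrics <- function(scores, labels, threshold) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sen <- if (n_pos > 0) mean(scores[labels == 1] >= threshold) else NA_real_
  spc <- if (n_neg > 0) mean(scores[labels == 0] < threshold) else NA_real_
  c(sensitivity = sen, specificity = spc, gap = sen - spc,
    youden = sen + spc - 1, n_pos = n_pos, n_neg = n_neg)
}
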