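#' Confusion-matrix counts at a score threshold
#'
#' A sample is predicted positive iff its score is `>=` the threshold (the
#' same convention used throughout the curve construction). TPR = TP/(TP+FN),
#' FPR = FP/(FP+TN), precision = TP/(TP+FP).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 outcome vector of the same length.
#' @param threshold classification cutoff.
#' @return named numeric vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  check_scores_labels(scores, labels, need_both_classes = FALSE)
  pred <- scores >= threshold
  pos <- labels == 1
  c(
    tp = sum(pred & pos),
    fp = sum(pred & !pos),
    fn = sum(!pred & pos),
    tn = sum(!pred & !pos)
  )
}

check_scores_labels <- function(scores, labels, need_both_classes = TRUE) {
  if (length(scores) == 0L) abort("empty score vector")
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  if (need_both_classes && (all(labels == 1) || all(labels == 0))) {
    abort("both classes must be present (AUC undefined for one class)")
  }
  invisible(TRUE)
}

#' ROC and precision-recall curve points
#'
#' Sweeps the unique scores in descending order as thresholds (prediction
#' positive iff score `>=` threshold) and records TPR, FPR, precision and
#' recall at each. Sentinel rows pin the ROC endpoints: threshold `Inf`
#' gives `(0, 0)` with precision defined as 1 at zero predicted positives,
#' and threshold `-Inf` gives `(1, 1)` with precision equal to the
#' prevalence (the terminal row duplicates the lowest-threshold point and
#' adds no area).
#'
#' @inheritParams confusion_counts
#' @return tibble of class `curve_points` with columns `threshold`, `tpr`,
#'   `fpr`, `precision`, `recall`.
#' @export
curve_points <- function(scores, labels) {
  check_scores_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  pos_total <- sum(y == 1)
  neg_total <- sum(y == 0)
  # last index of each tie group = counts at threshold "this unique score"
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  out <- tibble::tibble(
    threshold = c(Inf, s[last], -Inf),
    tpr = c(0, tp / pos_total, 1),
    fpr = c(0, fp / neg_total, 1),
    precision = c(1, tp / (tp + fp), pos_total / (pos_total + neg_total)),
    recall = c(0, tp / pos_total, 1)
  )
  class(out) <- c("curve_points", class(out))
  out
}

#' Area under a ROC or precision-recall curve
#'
#' ROC area is the trapezoid integral of TPR over FPR — equal to the
#' probability that a random positive outscores a random negative (ties
#' counting one half). PR area uses the average-precision (right-step)
#' convention, summing precision times each recall increment; trapezoidal
#' interpolation in PR space is known to be biased and is not used.
#'
#' @param points a [curve_points()] tibble.
#' @param which `"roc"` or `"pr"`.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(points, which = c("roc", "pr")) {
  which <- match.arg(which)
  if (which == "roc") {
    x <- points$fpr
    y <- points$tpr
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  } else {
    sum(diff(points$recall) * points$precision[-1])
  }
}

#' Fraction of model weights present in an upload
#'
#' Nonzero entries of the processed gradient over the model's total weight
#' entries, together with the wire-size counters used for trans-information
#' accounting (entries on selected channels are transmitted even when their
#' gradient happens to be exactly zero).
#'
#' @param upload a [process_gradients()] result.
#' @param model the congruent [init_model()] object.
#' @return scalar fraction in `[0, 1]`, with attributes `n_nonzero`,
#'   `n_support` (wire entries) and `n_total`.
#' @export
upload_fraction <- function(upload, model) {
  if (!identical(
    vapply(upload$deltas, dim, integer(2)),
    vapply(model$weights, dim, integer(2))
  )) {
    abort("upload and model shapes differ")
  }
  structure(
    upload$n_nonzero / upload$n_total,
    n_nonzero = upload$n_nonzero,
    n_support = upload$n_support,
    n_total = upload$n_total
  )
}

#' Export curve points as CSV
#'
#' @param points a [curve_points()] tibble.
#' @param path output file.
#' @export
write_curve_csv <- function(points, path) {
  readr::write_csv(tibble::as_tibble(points), path)
  invisible(path)
}
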