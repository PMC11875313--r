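#' Confusion counts at a threshold
#'
#' Tallies the confusion matrix with the toxic class as positive: a sample is
#' predicted toxic when its score is greater than or equal to the threshold.
#' TP are toxic samples correctly called toxic, FP non-toxic samples called
#' toxic, TN correctly called non-toxic, FN toxic samples missed.
#'
#' @param labels Binary vector (1 = toxic).
#' @param scores Probability-of-toxic scores in \[0, 1\].
#' @param threshold Decision cutoff in \[0, 1\].
#' @return Named list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1L),
       FP = sum(pred == 1L & labels == 0L),
       TN = sum(pred == 0L & labels == 0L),
       FN = sum(pred == 0L & labels == 1L))
}

#' Confusion-derived scalar metrics
#'
#' Computes accuracy, sensitivity (recall), specificity, precision, F1,
#' Matthews correlation coefficient, and balanced accuracy from confusion
#' counts, each by its textbook formula. Undefined ratios from zero
#' denominators return 0 (precision with no positive predictions; MCC with a
#' zero factor under the root), so degenerate classifiers score conservatively
#' rather than erroring.
#'
#' @param counts Output of [confusion()].
#' @return Named list of scalars.
#' @export
scalar_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sens <- safe_div(TP, TP + FN)
  spec <- safe_div(TN, TN + FP)
  prec <- safe_div(TP, TP + FP)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  mcc_den2 <- as.double(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (mcc_den2 == 0) 0 else
    (as.double(TP) * TN - as.double(FP) * FN) / sqrt(mcc_den2)
  list(accuracy = safe_div(TP + TN, n),
       sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, mcc = mcc, balanced_accuracy = (sens + spec) / 2)
}

# Internal: order scores descending and collapse tied scores into threshold
# groups. Returns cumulative TP/FP after each distinct threshold.
threshold_sweep <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- as.integer(labels[o])
  distinct <- !duplicated(s)
  grp <- cumsum(distinct)
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- which(c(distinct[-1], TRUE))        # last index of each tie group
  list(thresholds = s[distinct], tp = tp[last], fp = fp[last],
       P = sum(l), N = sum(1L - l))
}

#' Precision-recall curve and average precision
#'
#' Sweeps all distinct score values as thresholds (score >= threshold predicts
#' toxic). The area is the average precision: the step-wise sum of precision
#' times the recall increment, which avoids the optimistic linear
#' interpolation of a trapezoidal PR area. The no-skill baseline of this curve
#' equals the class prevalence.
#'
#' @inheritParams confusion
#' @return Object of class `nanotox_curve` with `points` (recall, precision),
#'   `thresholds`, `area`, and `baseline` (prevalence).
#' @export
pr_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  if (all(labels == 1L)) stop("labels contain no negative class")
  if (all(labels == 0L)) stop("labels contain no positive class")
  sw <- threshold_sweep(labels, scores)
  recall <- sw$tp / sw$P
  precision <- ifelse(sw$tp + sw$fp == 0, 1, sw$tp / (sw$tp + sw$fp))
  d_recall <- diff(c(0, recall))
  area <- sum(precision * d_recall)
  structure(list(points = data.frame(x = recall, y = precision),
                 thresholds = sw$thresholds, area = area,
                 baseline = sw$P / (sw$P + sw$N), type = "pr"),
            class = "nanotox_curve")
}

#' ROC curve and area
#'
#' The area equals the probability that a randomly chosen toxic sample
#' outranks a randomly chosen non-toxic one, with tied scores counting one
#' half (computed via the rank statistic, then cross-checkable against the
#' trapezoid over the tie-grouped curve).
#'
#' @inheritParams confusion
#' @return Object of class `nanotox_curve` with `points` (FPR, TPR),
#'   `thresholds`, `area`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  if (all(labels == 1L)) stop("labels contain no negative class")
  if (all(labels == 0L)) stop("labels contain no positive class")
  sw <- threshold_sweep(labels, scores)
  tpr <- sw$tp / sw$P
  fpr <- sw$fp / sw$N
  # concordance via midranks: ties contribute 1/2
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - sw$P * (sw$P + 1) / 2) / (as.double(sw$P) * sw$N)
  structure(list(points = data.frame(x = c(0, fpr), y = c(0, tpr)),
                 thresholds = sw$thresholds, area = auc, type = "roc"),
            class = "nanotox_curve")
}

#' @export
print.nanotox_curve <- function(x, ...) {
  cat(toupper(x$type), " curve: ", nrow(x$points), " points, area = ",
      format(x$area, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.nanotox_curve <- function(x, ...) {
  lab <- if (x$type == "pr") c("Recall", "Precision") else c("FPR", "TPR")
  plot(x$points$x, x$points$y, type = "l", xlab = lab[1], ylab = lab[2],
       xlim = c(0, 1), ylim = c(0, 1), ...)
  if (x$type == "pr") abline(h = x$baseline, lty = 2) else abline(0, 1, lty = 2)
  invisible(x)
}

#' F1-maximizing decision threshold
#'
#' Scans every distinct score (plus a sentinel above the maximum, representing
#' the all-negative classifier) and returns the threshold attaining the global
#' maximum F1; ties break toward the larger threshold.
#'
#' @inheritParams confusion
#' @return Scalar threshold.
#' @export
tune_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  if (all(labels == 1L)) stop("labels contain no negative class")
  if (all(labels == 0L)) stop("labels contain no positive class")
  sw <- threshold_sweep(labels, scores)
  prec <- ifelse(sw$tp + sw$fp == 0, 0, sw$tp / (sw$tp + sw$fp))
  rec <- sw$tp / sw$P
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  cand <- c(sw$thresholds, max(scores) + 1)   # sentinel: predict nothing toxic
  f1 <- c(f1, 0)
  # ties toward the larger threshold
  max(cand[f1 == max(f1)])
}

#' Full metric report for a scored test set
#'
#' Bundles the scalar metrics at an operating threshold with PR and ROC areas.
#'
#' @inheritParams confusion
#' @param threshold Operating cutoff; if `NULL`, tuned by [tune_threshold()].
#' @return Object of class `nanotox_report`: scalars plus `pr_auc`, `roc_auc`,
#'   `threshold`, and `n`.
#' @export
metric_report <- function(labels, scores, threshold = NULL) {
  if (is.null(threshold)) threshold <- tune_threshold(labels, scores)
  out <- scalar_metrics(confusion(labels, scores, threshold))
  out$pr_auc <- pr_curve(labels, scores)$area
  out$roc_auc <- roc_curve(labels, scores)$area
  out$threshold <- threshold
  out$n <- length(labels)
  structure(out, class = "nanotox_report")
}

#' @export
print.nanotox_report <- function(x, ...) {
  cat("Classification report (n = ", x$n, ", threshold = ",
      format(x$threshold, digits = 3), ")\n", sep = "")
  for (m in c("pr_auc", "roc_auc", "sensitivity", "precision", "f1", "mcc",
              "balanced_accuracy", "accuracy", "specificity"))
    cat(sprintf("  %-18s %.4f\n", m, x[[m]]))
  invisible(x)
}
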