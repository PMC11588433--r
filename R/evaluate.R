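#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of positive-negative score pairs ordered correctly, with
#' ties counted one half. Computed from ranks, so it is exact.
#'
#' @param scores Numeric classifier scores (higher = more advanced).
#' @param labels Binary class labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  assert_binary_labels(labels, length(scores))
  y <- label_to_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with trapezoidal AUC
#'
#' Thresholds are placed at the unique score values (a sample is called
#' positive when its score is >= the threshold), giving a monotone curve
#' from (0, 0) to (1, 1) whose trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary class labels.
#' @return Object of class `roc_analysis`: `points` tibble (`threshold`,
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  assert_binary_labels(labels, length(scores))
  y <- label_to_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  points <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc, n_pos = n1, n_neg = n0,
                 scores = scores, labels = label_to_binary(labels)),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("<roc_analysis> AUC =", signif(x$auc, 4),
      sprintf("(%d positive / %d negative)\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `roc_analysis`.
#' @param ... Unused.
#' @method tidy roc_analysis
#' @export
tidy.roc_analysis <- function(x, ...) x$points

#' DeLong confidence interval for an AUC
#'
#' Standard placement-based variance estimator.
#'
#' @param roc A `roc_analysis`.
#' @param level Confidence level.
#' @return Tibble: `auc`, `lower`, `upper`, `se`.
#' @export
delong_ci <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "roc_analysis"))
  s <- roc$scores; y <- roc$labels
  pos <- s[y == 1]; neg <- s[y == 0]
  v10 <- vapply(pos, function(p) (sum(neg < p) + 0.5 * sum(neg == p)) / length(neg), numeric(1))
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / length(pos), numeric(1))
  se <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble(auc = roc$auc,
         lower = max(0, roc$auc - z * se),
         upper = min(1, roc$auc + z * se),
         se = se)
}

#' Youden-optimal operating point
#'
#' The threshold maximising `J = sensitivity + specificity - 1`
#' (equivalently TPR - FPR); ties resolve to the lower threshold. A
#' degenerate curve (no threshold beats chance) is flagged.
#'
#' @param roc A `roc_analysis`.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden`, `degenerate`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_analysis"))
  pts <- roc$points[is.finite(roc$points$threshold), ]
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  pick <- best[which.min(pts$threshold[best])]
  tibble(threshold = pts$threshold[pick],
         sensitivity = pts$tpr[pick],
         specificity = 1 - pts$fpr[pick],
         youden = j[pick],
         degenerate = max(j) <= 0)
}

#' Full evaluation report: ROC, AUC, Youden operating point
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary class labels.
#' @param ci Include a DeLong confidence interval?
#' @return Object of class `evaluation_report`: `roc`, `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `youden`, optional `ci`.
#' @export
evaluation_report <- function(scores, labels, ci = FALSE) {
  roc <- roc_curve(scores, labels)
  yt <- youden_threshold(roc)
  structure(
    list(roc = roc, auc = roc$auc, threshold = yt$threshold,
         sensitivity = yt$sensitivity, specificity = yt$specificity,
         youden = yt$youden, degenerate = yt$degenerate,
         ci = if (ci) delong_ci(roc) else NULL),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> AUC = %.3f | Youden threshold = %.3f | sensitivity = %.1f%% | specificity = %.1f%%\n",
    x$auc, x$threshold, 100 * x$sensitivity, 100 * x$specificity))
  if (!is.null(x$ci)) {
    cat(sprintf("  DeLong %d%% CI: [%.3f, %.3f]\n", 95, x$ci$lower, x$ci$upper))
  }
  invisible(x)
}

#' @rdname evaluation_report
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(auc = x$auc, threshold = x$threshold, sensitivity = x$sensitivity,
         specificity = x$specificity, youden = x$youden,
         degenerate = x$degenerate)
}
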