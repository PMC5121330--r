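# Evaluation: confusion counts at a cutoff, threshold metrics, PR and ROC
# curves, trapezoidal AUC and the positive-fraction random baseline.
# A score is called positive when it is strictly above the cutoff; any
# zero-denominator ratio (including MCC's) is 0 by convention.

#' Confusion counts at a score cutoff
#'
#' Predicted positive iff `score > cutoff` (strict).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels (0/1), same length.
#' @param cutoff Score cutoff.
#' @return One-row tibble with integer columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, cutoff) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  stopifnot(all(labels %in% c(0, 1)))
  pred <- scores > cutoff
  pos <- labels == 1
  tibble::tibble(TP = sum(pred & pos), FP = sum(pred & !pos),
                 TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' Threshold metrics from confusion counts
#'
#' precision = TP/(TP+FP); recall (= sensitivity = TPR) = TP/(TP+FN);
#' specificity = TN/(TN+FP); FPR = FP/(FP+TN); ACC = (TP+TN)/total;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any 0/0 is 0.
#'
#' @param counts One-row tibble (or list) with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble: `precision`, `recall`, `specificity`, `fpr`,
#'   `acc`, `mcc`.
#' @export
metric_set <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion table", call. = FALSE)
  div0 <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  tibble::tibble(
    precision = div0(tp, tp + fp),
    recall = div0(tp, tp + fn),
    specificity = div0(tn, tn + fp),
    fpr = div0(fp, fp + tn),
    acc = (tp + tn) / total,
    mcc = div0(tp * tn - fp * fn, mcc_den)
  )
}

curve_points <- function(scores, labels, cutoffs) {
  dplyr::bind_rows(lapply(cutoffs, function(t) {
    dplyr::bind_cols(tibble::tibble(cutoff = t),
                     metric_set(confusion(scores, labels, t)))
  }))
}

#' Precision-recall and ROC curves
#'
#' One point per distinct score used as the cutoff (ties grouped), strictly
#' decreasing in cutoff; the ROC curve additionally carries the `(0, 0)` and
#' `(1, 1)` anchors (cutoffs `Inf` and `-Inf`). The PRC omits cutoffs at
#' which nothing is predicted positive (precision is undefined there),
#' starts from the conventional `(recall 0, precision 1)` anchor, and stops
#' at the first cutoff reaching full recall (lower cutoffs add no ranking
#' information, only diluted precision). Requires both classes present.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return Tibble of class `na_curve` with columns `cutoff`, `x`, `y` and
#'   attribute `kind` (`"PRC"` or `"ROC"`); for the PRC `x` is recall and
#'   `y` precision, for the ROC `x` is FPR and `y` TPR.
#' @export
pr_curve <- function(scores, labels) {
  check_two_classes(labels)
  cuts <- sort(unique(scores), decreasing = TRUE)
  cuts <- cuts[vapply(cuts, function(t) any(scores > t), logical(1))]
  pts <- curve_points(scores, labels, cuts)
  if (any(pts$recall == 1)) {
    pts <- pts[seq_len(which(pts$recall == 1)[1]), ]
  }
  out <- tibble::tibble(cutoff = c(Inf, pts$cutoff),
                        x = c(0, pts$recall), y = c(1, pts$precision))
  new_curve(out, "PRC")
}

#' @rdname pr_curve
#' @export
roc_curve <- function(scores, labels) {
  check_two_classes(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- curve_points(scores, labels, cuts)
  out <- tibble::tibble(cutoff = pts$cutoff, x = pts$fpr, y = pts$recall)
  new_curve(out, "ROC")
}

check_two_classes <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
}

new_curve <- function(tbl, kind) {
  attr(tbl, "kind") <- kind
  class(tbl) <- c("na_curve", setdiff(class(tbl), "na_curve"))
  tbl
}

#' Trapezoidal area under a curve
#'
#' @param curve An `na_curve` (or any tibble with `x` and `y`).
#' @return The trapezoidal area over the x-sorted points.
#' @export
auc <- function(curve) {
  if (nrow(curve) < 2) stop("curve has fewer than 2 points", call. = FALSE)
  o <- order(curve$x, curve$y)
  x <- curve$x[o]; y <- curve$y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Random-guess baseline
#'
#' The expected precision of a random predictor: the fraction of positive
#' examples.
#'
#' @param labels Binary labels (0/1).
#' @return Positives divided by total.
#' @export
random_baseline <- function(labels) {
  stopifnot(length(labels) > 0, all(labels %in% c(0, 1)))
  mean(labels == 1)
}

#' Metrics table over a grid of cutoffs
#'
#' @param scores Numeric scores; @param labels binary labels.
#' @param cutoffs Cutoff grid (default 0, 0.1, ..., 1).
#' @return Tibble: one row per cutoff with confusion counts and all metrics.
#' @export
metrics_by_cutoff <- function(scores, labels, cutoffs = seq(0, 1, 0.1)) {
  dplyr::bind_rows(lapply(cutoffs, function(t) {
    cf <- confusion(scores, labels, t)
    dplyr::bind_cols(tibble::tibble(cutoff = t), cf, metric_set(cf))
  }))
}
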