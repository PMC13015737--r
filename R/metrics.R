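#' Confusion counts for one-vs-rest classification
#'
#' @param truth vector of true labels.
#' @param pred vector of predicted labels (same length).
#' @param positive the label treated as the positive class.
#' @return A `confusion_counts` object with fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  if (length(truth) != length(pred))
    stop("'truth' and 'pred' differ in length", call. = FALSE)
  tpos <- truth == positive
  ppos <- pred == positive
  structure(list(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
                 FN = sum(tpos & !ppos), TN = sum(!tpos & !ppos)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is their
#' harmonic mean. A zero denominator yields a 0 for that metric with
#' `degenerate = TRUE` (consistent with reported per-class F1 values of
#' 0.00 for never-predicted classes).
#'
#' @param counts a [confusion_counts()] object, or `TP` given as a count
#'   together with `FP` and `FN`.
#' @param FP,FN false positive / false negative counts when `counts` is a
#'   bare `TP` count.
#' @return A list with `precision`, `recall`, `f1` and logical `degenerate`.
#' @export
precision_recall_f1 <- function(counts, FP = NULL, FN = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  } else {
    tp <- counts; fp <- FP; fn <- FN
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degen <- FALSE
  if (tp + fp > 0) prec <- tp / (tp + fp) else { prec <- 0; degen <- TRUE }
  if (tp + fn > 0) rec <- tp / (tp + fn) else { rec <- 0; degen <- TRUE }
  list(precision = prec, recall = rec, f1 = f1_score(prec, rec),
       degenerate = degen)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' `2 * precision * recall / (precision + recall)`, and 0 when both are 0.
#' Vectorized, so printed precision/recall columns can be turned into F1
#' columns directly.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 values in `[0, 1]`.
#' @examples
#' f1_score(0.69, 0.91)  # 0.785 -> prints as 0.78 at two decimals
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Macro-averaged F1 over classes
#'
#' Unweighted mean of per-class one-vs-rest F1 scores.
#'
#' @param truth,pred label vectors.
#' @param classes classes to average over (defaults to those in `truth`).
#' @return A list with `per_class` (named F1 vector) and `macro_f1`.
#' @export
macro_f1 <- function(truth, pred, classes = sort(unique(truth))) {
  per <- vapply(classes, function(cl) {
    precision_recall_f1(confusion_counts(truth, pred, cl))$f1
  }, numeric(1))
  names(per) <- as.character(classes)
  list(per_class = per, macro_f1 = mean(per))
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation, which equals the
#' trapezoidal area under the ROC curve with tied scores contributing 1/2 per
#' tied positive-negative pair. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (logical, 0/1, or a factor whose second level
#'   is positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' differ in length", call. = FALSE)
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Intersection over union and Dice coefficient of binary masks
#'
#' `iou()` returns `|A .. B| / |A .. B|` (Jaccard index); `dsc()` returns
#' `2 |A .. B| / (|A| + |B|)`. For any single mask pair the identity
#' `DSC = 2 IoU / (1 + IoU)` holds exactly -- but not for dataset means of
#' either metric. Two empty masks count as perfect agreement on absence:
#' both metrics return 1 with attribute `degenerate = TRUE` (other
#' conventions return 0 or NaN; the flag lets callers choose).
#'
#' @param pred,truth binary matrices (logical or 0/1) of identical shape.
#' @return A value in `[0, 1]`.
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[1:2, 2:3] <- 1
#' iou(a, b)  # overlap 2, union 6 -> 1/3
#' dsc(a, b)  # 2 * 2 / (4 + 4) -> 0.5
#' @export
iou <- function(pred, truth) {
  ab <- binarize_pair(pred, truth)
  inter <- sum(ab$a & ab$b); uni <- sum(ab$a | ab$b)
  if (uni == 0L) return(structure(1, degenerate = TRUE))
  inter / uni
}

#' @rdname iou
#' @export
dsc <- function(pred, truth) {
  ab <- binarize_pair(pred, truth)
  tot <- sum(ab$a) + sum(ab$b)
  if (tot == 0L) return(structure(1, degenerate = TRUE))
  2 * sum(ab$a & ab$b) / tot
}

binarize_pair <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  a <- as_array(pred) > 0.5
  b <- as_array(truth) > 0.5
  list(a = a, b = b)
}

#' Round for reporting (2 decimals, half to even)
#'
#' All computation in this package is done in full precision; this helper is
#' the single reporting-layer rounding rule used when comparing against
#' two-decimal printed tables.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
report_round <- function(x, digits = 2) round(x, digits)
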