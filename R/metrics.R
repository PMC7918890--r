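#' Soft dice loss
#'
#' Differentiable complement of the dice overlap used to train volumetric
#' segmentation networks:
#' \deqn{DL = 1 - \frac{2\sum_i p_i g_i + \epsilon}
#'                    {\sum_i p_i^2 + \sum_i g_i^2 + \epsilon},}
#' where \eqn{p_i \in [0,1]} are predicted probabilities, \eqn{g_i \in \{0,1\}}
#' the ground-truth labels, and the stabilizer \eqn{\epsilon = 10^{-5}}
#' prevents divergence when both masks are empty.
#'
#' @param pred 3D array of predicted probabilities in \[0, 1\].
#' @param truth 3D binary array (values in \{0, 1\}).
#' @param eps stabilizing constant (default `1e-5`).
#' @return Scalar loss in \[0, 1); exactly 0 for a perfect binary prediction.
#' @export
soft_dice_loss <- function(pred, truth, eps = 1e-5) {
  check_volume(pred, "pred"); check_volume(truth, "truth")
  check_same_shape(pred, truth)
  check_binary(truth, "truth")
  if (any(pred < 0 | pred > 1))
    stop("'pred' must lie in [0, 1]", call. = FALSE)
  stopifnot(eps > 0)
  num <- 2 * sum(pred * truth) + eps
  den <- sum(pred^2) + sum(truth^2) + eps
  1 - num / den
}

#' Hard dice score
#'
#' Voxel overlap \eqn{2|A \cap B| / (|A| + |B|)} between two binary masks.
#' When both masks are empty the score is 1 by convention (a correct
#' prediction of absence).
#'
#' @param pred,truth 3D binary arrays of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
dice_score <- function(pred, truth) {
  check_volume(pred, "pred"); check_volume(truth, "truth")
  check_same_shape(pred, truth)
  check_binary(pred, "pred"); check_binary(truth, "truth")
  tot <- sum(pred) + sum(truth)
  if (tot == 0) return(1)
  2 * sum(pred * truth) / tot
}

#' Voxel-wise confusion counts
#'
#' Tallies true/false positives/negatives between a predicted and a truth
#' mask. The four counts always partition the voxel total.
#'
#' @param pred,truth 3D binary arrays of the same shape.
#' @return An object of class `confusion_counts` with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  check_volume(pred, "pred"); check_volume(truth, "truth")
  check_same_shape(pred, truth)
  check_binary(pred, "pred"); check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  new_confusion_counts(tp, tn, fp, fn)
}

#' Construct confusion counts from the four tallies
#'
#' @param tp,tn,fp,fn non-negative voxel counts.
#' @return A `confusion_counts` object.
#' @export
new_confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d  TN %d  FP %d  FN %d  (total %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Pool confusion counts over cases
#'
#' @param ... `confusion_counts` objects, or a single list of them.
#' @return The elementwise sum as one `confusion_counts` object.
#' @export
pool_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && !inherits(cs[[1L]], "confusion_counts"))
    cs <- cs[[1L]]
  stopifnot(all(vapply(cs, inherits, logical(1), "confusion_counts")))
  tot <- function(field) sum(vapply(cs, function(x) as.numeric(x[[field]]),
                                    numeric(1)))
  new_confusion_counts(tot("tp"), tot("tn"), tot("fp"), tot("fn"))
}

metric_from_counts <- function(c, num, den, name) {
  stopifnot(inherits(c, "confusion_counts"))
  if (den == 0) stop(sprintf("%s undefined: zero denominator", name),
                     call. = FALSE)
  num / den
}

#' Accuracy, recall and precision from pooled confusion counts
#'
#' The standard voxel-pooled indicators:
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Recall (sensitivity) = TP/(TP+FN),
#' Precision = TP/(TP+FP). Full precision is returned;
#' [reported_metrics()] reproduces printed-table rounding.
#'
#' @param c a `confusion_counts` object.
#' @return Scalar in \[0, 1\].
#' @export
accuracy <- function(c)
  metric_from_counts(c, c$tp + c$tn, c$tp + c$tn + c$fp + c$fn, "accuracy")

#' @rdname accuracy
#' @export
recall <- function(c) metric_from_counts(c, c$tp, c$tp + c$fn, "recall")

#' @rdname accuracy
#' @export
precision <- function(c) metric_from_counts(c, c$tp, c$tp + c$fp, "precision")

#' Indicators at printed-table precision
#'
#' Rounds the three indicators the way confusion-matrix tables in this field
#' print them: accuracy to 4 decimals, recall and precision to 2, with
#' half-up rounding ([round_half_up()]).
#'
#' @param c a `confusion_counts` object.
#' @return Named list with `accuracy`, `recall`, `precision`.
#' @export
reported_metrics <- function(c) {
  list(accuracy  = round_half_up(accuracy(c), 4),
       recall    = round_half_up(recall(c), 2),
       precision = round_half_up(precision(c), 2))
}

#' Decompose tumor labels into nested evaluation regions
#'
#' BraTS-style label volumes code each voxel as 0 (background), 1 (necrotic
#' and non-enhancing tumor core), 2 (peritumoral edema) or 4 (enhancing
#' tumor). Evaluation uses three nested binary regions: enhancing tumor
#' ET = \{4\}, tumor core TC = \{1, 4\}, and whole tumor WT = \{1, 2, 4\},
#' so ET is a subset of TC is a subset of WT by construction.
#'
#' @param labels 3D array of integer codes in \{0, 1, 2, 4\}.
#' @return Named list of binary 3D arrays `WT`, `TC`, `ET`.
#' @export
label_decompose <- function(labels) {
  check_volume(labels, "labels")
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2, 4))
  if (length(bad) > 0L)
    stop(sprintf("unknown label codes: {%s}",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  as_mask <- function(codes) array((labels %in% codes) * 1L, dim = dim(labels))
  list(WT = as_mask(c(1, 2, 4)), TC = as_mask(c(1, 4)), ET = as_mask(4))
}
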