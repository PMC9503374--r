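#' Pixel confusion counts of a predicted mask
#'
#' Binarises the probability map at `threshold` (a pixel is predicted
#' positive when `pred >= threshold`) and counts true/false
#' positives/negatives against the binary ground truth. The four counts
#' always partition the evaluated pixels.
#'
#' @param pred Numeric array/matrix of per-pixel probabilities in `[0, 1]`
#'   (an already-binary mask works too).
#' @param gt Binary ground-truth mask of identical shape.
#' @param threshold Binarisation threshold, default 0.5.
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_from_masks(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_from_masks <- function(pred, gt, threshold = 0.5) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("pred and gt must have identical shapes", call. = FALSE)
  gv <- as.numeric(gt)
  if (!all(gv %in% c(0, 1))) stop("gt must be strictly binary", call. = FALSE)
  pv <- as.numeric(pred) >= threshold
  gv <- gv == 1
  confusion_counts(tp = sum(pv & gv), fp = sum(pv & !gv),
                   fn = sum(!pv & gv), tn = sum(!pv & !gv))
}

#' @rdname confusion_from_masks
#' @param tp,fp,fn,tn Non-negative pixel counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

# Zero-denominator convention: a ratio whose denominator vanishes is 1
# when prediction and truth are both empty of positives (the ideal is
# vacuously met) and 0 otherwise.
vacuous <- function(c) as.numeric(c$tp + c$fp + c$fn == 0)

ratio_or <- function(num, den, c) if (den == 0) vacuous(c) else num / den

#' Confusion-count segmentation metrics
#'
#' The six standard overlap metrics computed from pixel confusion
#' counts: Dice `2tp / (2tp + fp + fn)`, IoU `tp / (tp + fp + fn)`,
#' recall `tp / (tp + fn)`, precision `tp / (tp + fp)`, the
#' recall-weighted F2 score `5pr / (4p + r)`, and accuracy
#' `(tp + tn) / (tp + tn + fp + fn)`. All values lie in `[0, 1]`. When a
#' denominator vanishes the metric is 1 if prediction and truth are both
#' all-background, else 0.
#'
#' @param c A [confusion_counts()] object.
#' @return A numeric scalar in `[0, 1]`.
#' @examples
#' cc <- confusion_counts(tp = 3, fp = 1, fn = 2, tn = 4)
#' dice(cc); iou(cc); accuracy(cc)
#' @export
dice <- function(c) ratio_or(2 * c$tp, 2 * c$tp + c$fp + c$fn, c)

#' @rdname dice
#' @export
iou <- function(c) ratio_or(c$tp, c$tp + c$fp + c$fn, c)

#' @rdname dice
#' @export
recall <- function(c) ratio_or(c$tp, c$tp + c$fn, c)

#' @rdname dice
#' @export
precision <- function(c) ratio_or(c$tp, c$tp + c$fp, c)

#' @rdname dice
#' @export
f2 <- function(c) {
  p <- precision(c); r <- recall(c)
  if (4 * p + r == 0) return(vacuous(c))
  5 * p * r / (4 * p + r)
}

#' @rdname dice
#' @export
accuracy <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot == 0) return(1)
  (c$tp + c$tn) / tot
}

all_metrics <- function(c)
  c(mdice = dice(c), miou = iou(c), recall = recall(c),
    precision = precision(c), f2 = f2(c), accuracy = accuracy(c))

#' Evaluate a set of predicted masks
#'
#' Computes the six metrics over paired prediction/ground-truth lists
#' under both aggregation modes: `per_image_mean` averages each metric
#' computed per image (the convention behind "mean Dice"), while
#' `global_counts` first pools the confusion counts over all pixels of
#' all images and then evaluates the formulas once. Under pooled counts
#' Dice and IoU obey the identity `dice = 2 iou / (1 + iou)`; per-image
#' means do not, which is why both modes are always reported.
#'
#' @param pred_masks,gt_masks Equal-length lists of probability maps and
#'   binary masks with matching shapes.
#' @param threshold Binarisation threshold for predictions.
#' @param aggregation Which mode is the report's primary one.
#' @return An object of class `metric_report`: a list with
#'   `per_image_mean` and `global_counts` (each a named vector of the six
#'   metrics), the pooled `counts`, `n_images`, `threshold` and the
#'   primary `aggregation` label.
#' @examples
#' gt <- list(matrix(c(1, 0, 1, 0), 2))
#' evaluate_set(gt, gt)$global_counts[["mdice"]]
#' @export
evaluate_set <- function(pred_masks, gt_masks, threshold = 0.5,
                         aggregation = c("per_image_mean", "global_counts")) {
  aggregation <- match.arg(aggregation)
  if (length(pred_masks) == 0L) stop("empty evaluation set", call. = FALSE)
  if (length(pred_masks) != length(gt_masks))
    stop("pred_masks and gt_masks must have equal length", call. = FALSE)
  per <- vapply(seq_along(pred_masks), function(i)
    all_metrics(confusion_from_masks(pred_masks[[i]], gt_masks[[i]],
                                     threshold)),
    numeric(6))
  pooled <- confusion_counts(0, 0, 0, 0)
  for (i in seq_along(pred_masks)) {
    ci <- confusion_from_masks(pred_masks[[i]], gt_masks[[i]], threshold)
    for (f in names(ci)) pooled[[f]] <- pooled[[f]] + ci[[f]]
  }
  structure(list(per_image_mean = rowMeans(per),
                 global_counts = all_metrics(pooled),
                 counts = pooled, n_images = length(pred_masks),
                 threshold = threshold, aggregation = aggregation),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics over", x$n_images, "images (threshold",
      x$threshold, ")\n")
  tab <- rbind(per_image_mean = x$per_image_mean,
               global_counts = x$global_counts)
  print(round(tab, 4))
  cat("primary aggregation:", x$aggregation, "\n")
  invisible(x)
}
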