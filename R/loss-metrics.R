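# Soft Dice loss for training and the pixel-tally evaluation metrics.

#' Soft Dice loss
#'
#' \code{1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)}, computed per sample and averaged over the batch.  The
#' probability-weighted ("soft") form is differentiable; for binary inputs
#' it reduces to one minus the Dice coefficient.  The smoothing constant
#' keeps the ratio defined when both masks are empty (loss 0).
#'
#' @param pred_prob Numeric array of probabilities in [0, 1]: an (H, W)
#'   matrix, (H, W, 1) or (H, W, 1, N) array.
#' @param target Binary array of the same shape.
#' @param smooth Small positive smoothing constant (default 1e-6).
#' @return A scalar in [0, 1].
#' @export
dice_loss <- function(pred_prob, target, smooth = 1e-6) {
  pred_prob <- as_feature_map(pred_prob, "pred_prob")
  target <- as_feature_map(target, "target")
  if (!identical(dim(pred_prob), dim(target))) {
    stop("`pred_prob` and `target` shapes differ")
  }
  if (smooth <= 0) stop("`smooth` must be positive")
  op_dice_loss(NULL, op_input(NULL, pred_prob), target, smooth)$v
}

#' Pixel confusion counts
#'
#' Tallies true/false positives and negatives between two binary masks,
#' with foreground = 1.
#'
#' @param pred_binary,target_binary Equally shaped arrays with values in
#'   {0, 1}.
#' @return A list of class \code{confusion_counts} with integer fields
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn} summing to the pixel count.
#' @export
confusion_counts <- function(pred_binary, target_binary) {
  if (!identical(dim(pred_binary), dim(target_binary)) ||
      length(pred_binary) != length(target_binary)) {
    stop("mask shapes differ")
  }
  if (!all(pred_binary %in% c(0, 1)) || !all(target_binary %in% c(0, 1))) {
    stop("masks must be binary (values in {0, 1})")
  }
  p <- as.logical(pred_binary)
  t <- as.logical(target_binary)
  structure(list(
    tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t)
  ), class = "confusion_counts")
}

safe_ratio <- function(num, den, both_empty) {
  if (den == 0) return(if (both_empty) 1 else 0)
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Computes Dice = 2TP/(2TP+FP+FN), the foreground IoU TP/(TP+FP+FN)
#' (reported as \code{miou_paper}, the printed convention of the tables this
#' package mirrors), the two-class mean IoU (\code{iou_mean2class}, the mean
#' of foreground and background IoU, reported alongside for comparability
#' with other work), precision TP/(TP+FP), recall TP/(TP+FN) and their
#' harmonic mean F1.  Dice and F1 are algebraically identical when computed
#' from the same counts.  Any zero-denominator ratio is defined as 1 when
#' both masks are empty (a perfect trivial match) and 0 otherwise.
#'
#' @param counts A \code{\link{confusion_counts}} object (or a list with
#'   fields tp, fp, fn, tn).
#' @param printed_precision If TRUE, compute precision as TP/(TP+FN) — a
#'   formula some sources print that duplicates recall — for audit purposes
#'   only.  Default FALSE uses the standard TP/(TP+FP).
#' @return A list of class \code{metrics_report} with fields \code{dice},
#'   \code{miou_paper}, \code{iou_mean2class}, \code{precision},
#'   \code{recall}, \code{f1}, all in [0, 1].
#' @export
compute_metrics <- function(counts, printed_precision = FALSE) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  both_empty <- (tp + fp == 0) && (tp + fn == 0)
  dice <- safe_ratio(2 * tp, 2 * tp + fp + fn, both_empty)
  iou_fg <- safe_ratio(tp, tp + fp + fn, both_empty)
  both_full <- (tn + fp == 0) && (tn + fn == 0)
  iou_bg <- safe_ratio(tn, tn + fp + fn, both_full)
  precision <- if (printed_precision) {
    safe_ratio(tp, tp + fn, both_empty)
  } else {
    safe_ratio(tp, tp + fp, both_empty)
  }
  recall <- safe_ratio(tp, tp + fn, both_empty)
  f1 <- if (precision + recall == 0) {
    if (both_empty) 1 else 0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    dice = dice, miou_paper = iou_fg,
    iou_mean2class = (iou_fg + iou_bg) / 2,
    precision = precision, recall = recall, f1 = f1
  ), class = "metrics_report")
}

#' Aggregate per-image metrics
#'
#' Returns both aggregation conventions: the per-image mean of the supplied
#' reports, and the globally pooled metrics recomputed from the summed
#' confusion counts.  The two differ whenever images contribute unequal
#' foreground (e.g. empty-mask images pull the per-image mean).
#'
#' @param per_image Non-empty list of \code{\link{compute_metrics}} reports.
#' @param counts Non-empty list of matching \code{\link{confusion_counts}}.
#' @return A list with \code{mean} and \code{pooled}, each a
#'   \code{metrics_report}.
#' @export
aggregate_metrics <- function(per_image, counts) {
  if (length(per_image) == 0 || length(counts) == 0) {
    stop("`per_image` and `counts` must be non-empty")
  }
  if (length(per_image) != length(counts)) {
    stop("`per_image` and `counts` lengths differ")
  }
  fields <- c("dice", "miou_paper", "iou_mean2class", "precision",
              "recall", "f1")
  mean_rep <- lapply(fields, function(f) {
    mean(vapply(per_image, function(r) r[[f]], numeric(1)))
  })
  names(mean_rep) <- fields
  total <- list(
    tp = sum(vapply(counts, `[[`, numeric(1), "tp")),
    fp = sum(vapply(counts, `[[`, numeric(1), "fp")),
    fn = sum(vapply(counts, `[[`, numeric(1), "fn")),
    tn = sum(vapply(counts, `[[`, numeric(1), "tn"))
  )
  list(mean = structure(mean_rep, class = "metrics_report"),
       pooled = compute_metrics(total))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Dice %.4f | mIoU(fg) %.4f | IoU(2-class) %.4f | P %.4f | R %.4f | F1 %.4f\n",
    x$dice, x$miou_paper, x$iou_mean2class, x$precision, x$recall, x$f1))
  invisible(x)
}
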