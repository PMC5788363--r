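#' Overlap accuracy (Jaccard index in percent)
#'
#' `|A intersect B| / |A union B| * 100` between a segmented mask and a
#' ground-truth mask. (This quantity, conventionally the Jaccard index,
#' is reported as "accuracy" in the dermoscopy evaluation convention this
#' package follows.) Two empty masks are defined as 100% and reported via
#' a message.
#'
#' @param segmented,truth Binary matrices (0/1 or logical) of equal shape.
#' @return Scalar percent in \[0, 100\].
#' @export
overlap_accuracy <- function(segmented, truth) {
  a <- check_binary_pair(segmented, truth)
  inter <- sum(a$s & a$t)
  uni <- sum(a$s | a$t)
  if (uni == 0) {
    message("both masks empty; overlap accuracy defined as 100")
    return(100)
  }
  100 * inter / uni
}

#' Confusion counts between a segmentation and its ground truth
#'
#' Pixel counts with positive = inside the object: TP (segmented object
#' pixels), TN (correctly unsegmented background), FP (background called
#' object), FN (missed object pixels).
#'
#' @inheritParams overlap_accuracy
#' @return List of class `acseg_confusion` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(segmented, truth) {
  a <- check_binary_pair(segmented, truth)
  structure(list(tp = sum(a$s & a$t), tn = sum(!a$s & !a$t),
                 fp = sum(a$s & !a$t), fn = sum(!a$s & a$t)),
            class = "acseg_confusion")
}

#' Metric report from confusion counts
#'
#' Computes Dice `2TP / (2TP + FP + FN)`, sensitivity `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)` and overlap accuracy
#' `TP / (TP + FP + FN) * 100`. A metric whose denominator is zero is
#' reported as `NA` (undefined) and listed in the `undefined` field rather
#' than being coerced to 0 or 1.
#'
#' @param counts `acseg_confusion` from [confusion()], or a list with
#'   `tp`, `tn`, `fp`, `fn`.
#' @return List of class `acseg_metric_report` with `accuracy_pct`,
#'   `dice`, `sensitivity`, `specificity`, `undefined` (character vector
#'   of undefined metric names) and the counts.
#' @export
metric_report <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  dice <- safe(2 * tp, 2 * tp + fp + fn)
  sen <- safe(tp, tp + fn)
  spe <- safe(tn, tn + fp)
  acc <- safe(100 * tp, tp + fp + fn)
  und <- c("dice", "sensitivity", "specificity", "accuracy_pct")[
    is.na(c(dice, sen, spe, acc))]
  structure(list(accuracy_pct = acc, dice = dice, sensitivity = sen,
                 specificity = spe, undefined = und,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "acseg_metric_report")
}

#' Full evaluation of a segmentation against ground truth
#'
#' Convenience wrapper: confusion counts plus all metrics.
#'
#' @inheritParams overlap_accuracy
#' @return `acseg_metric_report` (see [metric_report()]).
#' @export
segmentation_metrics <- function(segmented, truth) {
  metric_report(confusion(segmented, truth))
}

#' Write a metric report to JSON
#'
#' @param report `acseg_metric_report`.
#' @param path Output file.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(accuracy_pct = report$accuracy_pct, dice = report$dice,
         sensitivity = report$sensitivity, specificity = report$specificity,
         tp = report$tp, tn = report$tn, fp = report$fp, fn = report$fn),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @export
print.acseg_metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  dice %.4f  sensitivity %.4f  specificity %.4f\n",
              x$accuracy_pct, x$dice, x$sensitivity, x$specificity))
  cat(sprintf("counts: TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

check_binary_pair <- function(segmented, truth) {
  if (!identical(dim(segmented), dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  s <- segmented != 0
  t <- truth != 0
  list(s = s, t = t)
}
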