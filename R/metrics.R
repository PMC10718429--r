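#' Pixel-wise confusion-matrix metrics
#'
#' Computes the ratio metrics of the evaluation suite from pooled ("micro")
#' pixel counts over all supplied masks: accuracy, precision,
#' sensitivity (= recall), specificity, F1, and the Jaccard index, together
#' with the hard Dice coefficient `2TP / (2TP + FP + FN)`.
#'
#' Zero-denominator conventions: a ratio whose denominator is empty is 1
#' when the associated error count is also zero (vacuously perfect, e.g.
#' an all-negative truth predicted all-negative) and 0 otherwise.
#'
#' @param y binary array/vector of ground truth.
#' @param p_bin binary array/vector of predictions, same shape.
#' @return a list with components `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `f1`, `dice`, `jaccard`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(y, p_bin) {
  check_same_shape(y, p_bin)
  if (!all(y %in% c(0, 1)) || !all(p_bin %in% c(0, 1)))
    stop("confusion_metrics expects strictly binary inputs")
  y <- as.numeric(y); p <- as.numeric(p_bin)
  tp <- sum(y == 1 & p == 1)
  fp <- sum(y == 0 & p == 1)
  tn <- sum(y == 0 & p == 0)
  fn <- sum(y == 1 & p == 0)
  ratio <- function(num, den, err) {
    if (den > 0) num / den else if (err == 0) 1 else 0
  }
  precision <- ratio(tp, tp + fp, fn)
  sensitivity <- ratio(tp, tp + fn, fp)
  f1 <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = precision,
    sensitivity = sensitivity,
    specificity = ratio(tn, tn + fp, fn),
    f1 = f1,
    dice = ratio(2 * tp, 2 * tp + fp + fn, fp + fn),
    jaccard = ratio(tp, tp + fp + fn, 0)
  )
}

#' Assemble the nine-column evaluation record
#'
#' Combines pooled confusion-matrix ratios on binarized predictions with the
#' soft-probability loss terms into one evaluation row. The Dice coefficient
#' and Jaccard index are reported on the binarized masks (hard form); `loss`
#' and `dice_loss` use the raw probabilities (soft form), mirroring how a
#' trained model is monitored versus how its final masks are scored.
#'
#' @param y binary ground-truth array.
#' @param probs predicted probabilities, same shape.
#' @param threshold binarization threshold in (0, 1).
#' @return one-row `data.frame` with columns `accuracy`, `loss`,
#'   `dice_loss`, `precision`, `f1`, `sensitivity`, `specificity`,
#'   `dice_coefficient`, `jaccard`.
#' @export
metrics_report <- function(y, probs, threshold = 0.4) {
  p_bin <- binarize(probs, threshold)
  cm <- confusion_metrics(y, p_bin)
  lt <- bce_dice_loss(y, probs)
  data.frame(
    accuracy = cm$accuracy,
    loss = lt$total,
    dice_loss = lt$dice_loss,
    precision = cm$precision,
    f1 = cm$f1,
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    dice_coefficient = cm$dice,
    jaccard = cm$jaccard
  )
}
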