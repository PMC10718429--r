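#' Segmentation losses: binary cross-entropy, Dice, and their sum
#'
#' The training objective is the sum of the mean binary cross-entropy over
#' all pixels and the Dice loss `1 - dice_coefficient(y, p)`. The Dice
#' coefficient is computed in its soft form, `2 * sum(y * p) /
#' (sum(y) + sum(p) + epsilon)`, so predicted probabilities can be used
#' directly; on binary inputs it reduces to the usual overlap ratio.
#' Predicted probabilities are clamped to `[clamp, 1 - clamp]` before the
#' logarithms in the cross-entropy.
#'
#' @param y numeric array of ground-truth labels in \{0, 1\}.
#' @param p numeric array of predicted probabilities, same shape as `y`.
#' @param epsilon smoothing constant in the Dice denominator (default 1e-5).
#' @param clamp probability clamping bound for the cross-entropy logs
#'   (default 1e-7).
#' @return `bce_loss`, `dice_coefficient` and `dice_loss` return a scalar.
#'   `bce_dice_loss` returns a list with components `bce`, `dice_loss`,
#'   `total` (their exact sum) and `epsilon`.
#' @examples
#' bce_loss(1, 0.5)                    # log(2)
#' dice_coefficient(c(1, 1), c(1, 0))  # ~ 2/3
#' bce_dice_loss(1, 0.5)$total
#' @name losses
NULL

check_same_shape <- function(y, p) {
  dy <- dim(y) %||% length(y)
  dp <- dim(p) %||% length(p)
  if (!identical(as.integer(dy), as.integer(dp)))
    stop("y and p must have the same shape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname losses
#' @export
bce_loss <- function(y, p, clamp = 1e-7) {
  check_same_shape(y, p)
  p <- pmin(pmax(p, clamp), 1 - clamp)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname losses
#' @export
dice_coefficient <- function(y, p, epsilon = 1e-5) {
  check_same_shape(y, p)
  2 * sum(y * p) / (sum(y) + sum(p) + epsilon)
}

#' @rdname losses
#' @export
dice_loss <- function(y, p, epsilon = 1e-5) 1 - dice_coefficient(y, p, epsilon)

#' @rdname losses
#' @export
bce_dice_loss <- function(y, p, epsilon = 1e-5, clamp = 1e-7) {
  bce <- bce_loss(y, p, clamp)
  dl <- dice_loss(y, p, epsilon)
  list(bce = bce, dice_loss = dl, total = bce + dl, epsilon = epsilon)
}
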