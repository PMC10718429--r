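#' Activation functions
#'
#' Elementwise nonlinearities used throughout the networks: the logistic
#' sigmoid, swish (`x * sigmoid(beta * x)`, beta fixed at 1 unless given),
#' mish (`x * tanh(softplus(x))`), ReLU and leaky ReLU. All are vectorised
#' and numerically stable for large `|x|`.
#'
#' Swish and mish are smooth and non-monotonic: both dip below zero for
#' moderately negative inputs before vanishing, which preserves a small
#' amount of negative signal compared with ReLU.
#'
#' @param x numeric vector/array.
#' @param beta slope of the sigmoid inside swish (default 1).
#' @param a negative-side slope for `leaky_relu` (default 0.1).
#' @return numeric object of the same shape as `x`.
#' @examples
#' sigmoid(0)        # 0.5
#' swish(1)          # 0.7310586
#' mish(1)           # 0.8650984
#' leaky_relu(-3)    # -0.3
#' @name activations
NULL

#' @rdname activations
#' @export
sigmoid <- function(x) {
  # stable in both tails: exp() of a non-positive argument only
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' @rdname activations
#' @export
swish <- function(x, beta = 1) x * sigmoid(beta * x)

softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @rdname activations
#' @export
mish <- function(x) x * tanh(softplus(x))

#' @rdname activations
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname activations
#' @export
leaky_relu <- function(x, a = 0.1) ifelse(x > 0, x, a * x)

# derivative lookup used by the backward pass; input is the pre-activation
activation_fun <- function(name, a = 0.1) {
  switch(name,
    relu = list(
      f = relu,
      grad = function(z) (z > 0) * 1.0
    ),
    leaky_relu = list(
      f = function(z) leaky_relu(z, a),
      grad = function(z) ifelse(z > 0, 1.0, a)
    ),
    swish = list(
      f = swish,
      grad = function(z) {
        s <- sigmoid(z)
        s + z * s * (1 - s)
      }
    ),
    mish = list(
      f = mish,
      grad = function(z) {
        sp <- softplus(z)
        t <- tanh(sp)
        t + z * (1 - t^2) * sigmoid(z)
      }
    ),
    sigmoid = list(
      f = sigmoid,
      grad = function(z) {
        s <- sigmoid(z)
        s * (1 - s)
      }
    ),
    stop("unknown activation: ", name)
  )
}
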