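#' The fixed 3x3 sharpening kernel
#'
#' Identity-plus-negative-Laplacian kernel
#' `[[0,-1,0],[-1,5,-1],[0,-1,0]]`. Its entries sum to 1, so it preserves
#' the DC component: constant feature maps are fixed points when combined
#' with edge-replicate padding.
#'
#' @return 3x3 numeric matrix.
#' @export
sharpening_kernel <- function() {
  matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3, byrow = TRUE)
}

#' Sharpen feature maps with a fixed depthwise kernel
#'
#' Convolves every channel of every batch element independently with the
#' sharpening kernel, using edge-replicate padding so the output has the
#' same spatial size and constant channels pass through unchanged. The
#' operation has no trainable parameters.
#'
#' @param x a matrix (H x W), a 3-D array (H, W, C) or a 4-D array
#'   (H, W, C, B).
#' @param k 3x3 kernel (default [sharpening_kernel()]).
#' @return object of the same shape as `x`.
#' @export
sharpen_features <- function(x, k = sharpening_kernel()) {
  d <- dim(x) %||% length(x)
  x4 <- as_tensor4(x)
  y <- nn_sharpen_fwd(x4, k)
  restore_shape(y, d)
}

as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("x must be at least 2-D")
  x <- as.numeric(x)
  dim(x) <- switch(as.character(length(d)),
                   "2" = c(d, 1L, 1L),
                   "3" = c(d, 1L),
                   "4" = d,
                   stop("x must be 2-D, 3-D or 4-D"))
  x
}

restore_shape <- function(y, d) {
  if (length(d) == 1) dim(y) <- NULL else dim(y) <- d
  y
}

#' Additive attention gate
#'
#' Computes per-pixel attention coefficients
#' `a = sigmoid(Ws %*% swish(Wx x + Wg g))` from the skip features `x` and a
#' spatially aligned gating signal `g`, where `Wx`, `Wg`, `Ws` are 1x1
#' channel-wise convolutions and both bias terms are fixed at zero. The
#' output is `x * a`, with the single-channel coefficient map broadcast over
#' the channels of `x`; coefficients are strictly inside (0, 1) for finite
#' inputs.
#'
#' @param x skip feature tensor (H, W, Cx, B) (lower-rank input is promoted).
#' @param g gating tensor of the same spatial size (H, W, Cg, B).
#' @param params list with 1x1 conv weights `Wx` (1,1,Cx,Ci), `Wg`
#'   (1,1,Cg,Ci) and `Ws` (1,1,Ci,1); scalars are accepted for 1-channel
#'   toys.
#' @return gated tensor shaped like `x`, with the coefficient map in
#'   attribute `"attention"`.
#' @export
attention_gate <- function(x, g, params) {
  dx0 <- dim(x) %||% length(x)
  x4 <- as_tensor4(if (is.null(dim(x))) matrix(x, 1, 1) else x)
  g4 <- as_tensor4(if (is.null(dim(g))) matrix(g, 1, 1) else g)
  if (!identical(dim(x4)[c(1, 2, 4)], dim(g4)[c(1, 2, 4)]))
    stop("x and g must be spatially aligned with equal batch")
  Wx <- as_w1(params$Wx, dim(x4)[3])
  Wg <- as_w1(params$Wg, dim(g4)[3])
  ci <- dim(Wx)[4]
  Ws <- as_w1(params$Ws, ci)
  f <- gate_fwd(x4, g4, Wx, Wg, Ws)
  out <- f$out
  if (length(dx0) == 1 && dx0 == 1) {
    out <- as.numeric(out)
    a <- as.numeric(f$a)
  } else {
    dim(out) <- if (length(dx0) > 1) dx0 else NULL
    a <- f$a
  }
  attr(out, "attention") <- a
  out
}

as_w1 <- function(w, cin) {
  if (is.null(dim(w))) {
    if (length(w) %% cin != 0) stop("1x1 weight size incompatible")
    dim(w) <- c(1, 1, cin, length(w) / cin)
  }
  w
}

gate_fwd <- function(x, g, Wx, Wg, Ws) {
  ci <- dim(Wx)[4]
  q <- nn_conv_fwd(x, Wx, numeric(ci)) + nn_conv_fwd(g, Wg, numeric(ci))
  s1 <- swish(q)
  u <- nn_conv_fwd(s1, Ws, 0)
  a <- sigmoid(u)
  cx <- dim(x)[3]
  out <- x * a[, , rep(1, cx), , drop = FALSE]
  list(out = out, q = q, s1 = s1, a = a)
}

gate_bwd <- function(dout, x, g, Wx, Wg, Ws, f) {
  cx <- dim(x)[3]
  ab <- f$a[, , rep(1, cx), , drop = FALSE]
  dx <- dout * ab
  da <- channel_sum(dout * x)
  du <- da * f$a * (1 - f$a)
  r3 <- nn_conv_bwd(f$s1, Ws, du)
  sgrad <- activation_fun("swish")$grad
  dq <- r3$dx * sgrad(f$q)
  r1 <- nn_conv_bwd(x, Wx, dq)
  r2 <- nn_conv_bwd(g, Wg, dq)
  list(dx = dx + r1$dx, dg = r2$dx,
       dWx = r1$dw, dWg = r2$dw, dWs = r3$dw)
}

channel_sum <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 1, d[4]))
  for (ci in seq_len(d[3])) out <- out + x[, , ci, , drop = FALSE]
  out
}

#' Declare an architecture variant
#'
#' @param variant one of `"unet"`, `"sharp"`, `"attention"`,
#'   `"sharp_attention"`. The variants differ only in what travels along the
#'   skip connections: raw encoder features; sharpened features (except at
#'   the deepest skip, where the sharpening filter is removed); attention-
#'   gated features; or the concatenation of both the gated and the
#'   sharpened features.
#' @param depth number of encoder levels before the bottleneck (default 4).
#' @param base_filters channels at the first level, doubling per level
#'   (default 16).
#' @param activation hidden-layer activation (default `"swish"`); the
#'   attention gates always use swish internally and the output head is
#'   always a sigmoid.
#' @param dropout_encoder,dropout_decoder dropout rates after the second
#'   convolution of each encoder (0.1) / decoder and bottleneck (0.5) block.
#' @param input_side expected input side; must be divisible by `2^depth`.
#' @param leaky_slope negative slope when `activation = "leaky_relu"`.
#' @return a `model_spec` list.
#' @export
model_spec <- function(variant = c("sharp_attention", "unet", "sharp",
                                   "attention"),
                       depth = 4, base_filters = 16, activation = "swish",
                       dropout_encoder = 0.1, dropout_decoder = 0.5,
                       input_side = 128, leaky_slope = 0.1) {
  variant <- match.arg(variant)
  if (input_side %% 2^depth != 0)
    stop("input_side must be divisible by 2^depth")
  activation_fun(activation, leaky_slope)  # validates the name
  structure(list(variant = variant, depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 activation = activation,
                 dropout_encoder = dropout_encoder,
                 dropout_decoder = dropout_decoder,
                 input_side = as.integer(input_side),
                 leaky_slope = leaky_slope),
            class = "model_spec")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build a model: initialize all trainable weights
#'
#' Encoder blocks use two 3x3 same-padding convolutions with the spec's
#' activation, dropout, then 2x2 max-pooling with channels doubling per
#' level; the decoder mirrors them with learned 2x2 stride-2 transposed
#' convolutions and channel-concatenated skips; a final 1x1 convolution plus
#' sigmoid yields the probability map. Weights use He-normal initialization;
#' attention-gate biases are fixed at zero and the sharpening kernel is
#' fixed, contributing no parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the weight initialization.
#' @return a `sharpseg_model` with elements `spec`, `params` (flat named
#'   list of arrays), `n_sharpen_sites`, `n_attention_gates`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  dep <- spec$depth
  f <- spec$base_filters * 2^(seq_len(dep) - 1)
  fb <- spec$base_filters * 2^dep
  use_sharp <- spec$variant %in% c("sharp", "sharp_attention")
  use_att <- spec$variant %in% c("attention", "sharp_attention")
  p <- list()
  with_seed(seed, {
    cin <- 1L
    for (l in seq_len(dep)) {
      p[[nm("enc", l, "W1")]] <- he_init(c(3, 3, cin, f[l]), 9 * cin)
      p[[nm("enc", l, "b1")]] <- numeric(f[l])
      p[[nm("enc", l, "W2")]] <- he_init(c(3, 3, f[l], f[l]), 9 * f[l])
      p[[nm("enc", l, "b2")]] <- numeric(f[l])
      cin <- f[l]
    }
    p[["bot.W1"]] <- he_init(c(3, 3, f[dep], fb), 9 * f[dep])
    p[["bot.b1"]] <- numeric(fb)
    p[["bot.W2"]] <- he_init(c(3, 3, fb, fb), 9 * fb)
    p[["bot.b2"]] <- numeric(fb)
    for (l in rev(seq_len(dep))) {
      cc <- if (l == dep) fb else f[l + 1]
      p[[nm("dec", l, "Wu")]] <- he_init(c(2, 2, cc, f[l]), 4 * cc)
      p[[nm("dec", l, "bu")]] <- numeric(f[l])
      ncat <- f[l] * (if (spec$variant == "sharp_attention") 3L else 2L)
      p[[nm("dec", l, "W1")]] <- he_init(c(3, 3, ncat, f[l]), 9 * ncat)
      p[[nm("dec", l, "b1")]] <- numeric(f[l])
      p[[nm("dec", l, "W2")]] <- he_init(c(3, 3, f[l], f[l]), 9 * f[l])
      p[[nm("dec", l, "b2")]] <- numeric(f[l])
      if (use_att) {
        ci <- max(1L, f[l] %/% 2L)
        p[[nm("att", l, "Wx")]] <- he_init(c(1, 1, f[l], ci), f[l])
        p[[nm("att", l, "Wg")]] <- he_init(c(1, 1, f[l], ci), f[l])
        p[[nm("att", l, "Ws")]] <- he_init(c(1, 1, ci, 1), ci)
      }
    }
    p[["out.W"]] <- he_init(c(1, 1, f[1], 1), f[1])
    p[["out.b"]] <- numeric(1)
  })
  structure(list(spec = spec, params = p,
                 n_sharpen_sites = if (use_sharp) dep - 1L else 0L,
                 n_attention_gates = if (use_att) dep else 0L),
            class = "sharpseg_model")
}

nm <- function(block, l, part) paste0(block, l, ".", part)

#' Count trainable parameters
#' @param model a `sharpseg_model`.
#' @return integer total number of trainable scalars.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.sharpseg_model <- function(x, ...) {
  cat(sprintf(
    "<sharpseg_model> variant=%s depth=%d base_filters=%d act=%s params=%d\n",
    x$spec$variant, x$spec$depth, x$spec$base_filters, x$spec$activation,
    count_params(x)))
  invisible(x)
}
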