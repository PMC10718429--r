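# Forward and backward passes for the U-Net family. Tensors are R arrays
# (H, W, C, B); the heavy lifting (convolutions, pooling, upsampling and
# their adjoints) lives in compiled code, while activations, dropout,
# concatenation and the attention gates are composed here.

conv_act_fwd <- function(x, W, b, act) {
  z <- nn_conv_fwd(x, W, b)
  list(x = x, z = z, y = act$f(z))
}

conv_act_bwd <- function(cb, W, dy, act) {
  dz <- dy * act$grad(cb$z)
  nn_conv_bwd(cb$x, W, dz)
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

cat_channels <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

split_channels <- function(x, cs) {
  at <- 0L
  out <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    out[[i]] <- x[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

# Forward pass. Returns logits z, probabilities p and (for training) the
# cache of intermediates needed by net_backward.
net_forward <- function(params, spec, x, train = FALSE) {
  act <- activation_fun(spec$activation, spec$leaky_slope)
  dep <- spec$depth
  K <- sharpening_kernel()
  variant <- spec$variant
  use_sharp <- variant %in% c("sharp", "sharp_attention")
  use_att <- variant %in% c("attention", "sharp_attention")
  cache <- list(enc = vector("list", dep), dec = vector("list", dep))
  h <- x
  for (l in seq_len(dep)) {
    c1 <- conv_act_fwd(h, params[[nm("enc", l, "W1")]],
                       params[[nm("enc", l, "b1")]], act)
    c2 <- conv_act_fwd(c1$y, params[[nm("enc", l, "W2")]],
                       params[[nm("enc", l, "b2")]], act)
    dp <- dropout_fwd(c2$y, spec$dropout_encoder, train)
    mp <- nn_maxpool_fwd(dp$y)
    cache$enc[[l]] <- list(c1 = c1, c2 = c2, mask = dp$mask,
                           mpidx = mp$idx, skip = dp$y)
    h <- mp$y
  }
  # bottleneck: two convolutions, no dropout (regularization lives in the
  # encoder/decoder blocks)
  b1 <- conv_act_fwd(h, params[["bot.W1"]], params[["bot.b1"]], act)
  b2 <- conv_act_fwd(b1$y, params[["bot.W2"]], params[["bot.b2"]], act)
  cache$bot <- list(c1 = b1, c2 = b2, mask = NULL)
  h <- b2$y
  for (l in rev(seq_len(dep))) {
    up_in <- h
    up <- nn_tconv_fwd(h, params[[nm("dec", l, "Wu")]],
                       params[[nm("dec", l, "bu")]])
    skip <- cache$enc[[l]]$skip
    lev <- list(up_in = up_in)
    parts <- list(up)
    if (use_att) {
      gf <- gate_fwd(skip, up, params[[nm("att", l, "Wx")]],
                     params[[nm("att", l, "Wg")]],
                     params[[nm("att", l, "Ws")]])
      lev$gate <- gf
      lev$up <- up  # gating signal, needed by the gate's backward pass
      parts <- c(parts, list(gf$out))
    }
    if (use_sharp) {
      # the deepest sharpening filter is removed: raw features pass through
      sh <- if (l == dep) skip else nn_sharpen_fwd(skip, K)
      lev$sharp_applied <- l != dep
      parts <- c(parts, list(sh))
    }
    if (!use_att && !use_sharp) parts <- c(parts, list(skip))
    cat <- cat_channels(parts)
    lev$cs <- vapply(parts, function(p) dim(p)[3], integer(1))
    d1 <- conv_act_fwd(cat, params[[nm("dec", l, "W1")]],
                       params[[nm("dec", l, "b1")]], act)
    d2 <- conv_act_fwd(d1$y, params[[nm("dec", l, "W2")]],
                       params[[nm("dec", l, "b2")]], act)
    ddp <- dropout_fwd(d2$y, spec$dropout_decoder, train)
    lev$c1 <- d1; lev$c2 <- d2; lev$mask <- ddp$mask
    cache$dec[[l]] <- lev
    h <- ddp$y
  }
  z <- nn_conv_fwd(h, params[["out.W"]], params[["out.b"]])
  cache$head_in <- h
  list(z = z, p = sigmoid(z), cache = cache)
}

# Backward pass from dL/dz (gradient at the logits). Returns the gradient
# list with the same names as params.
net_backward <- function(params, spec, fw, dz) {
  act <- activation_fun(spec$activation, spec$leaky_slope)
  dep <- spec$depth
  K <- sharpening_kernel()
  variant <- spec$variant
  use_sharp <- variant %in% c("sharp", "sharp_attention")
  use_att <- variant %in% c("attention", "sharp_attention")
  cache <- fw$cache
  gr <- list()
  rh <- nn_conv_bwd(cache$head_in, params[["out.W"]], dz)
  gr[["out.W"]] <- rh$dw; gr[["out.b"]] <- rh$db
  dh <- rh$dx
  dskip <- vector("list", dep)
  for (l in seq_len(dep)) {
    lev <- cache$dec[[l]]
    if (!is.null(lev$mask)) dh <- dh * lev$mask
    r2 <- conv_act_bwd(lev$c2, params[[nm("dec", l, "W2")]], dh, act)
    gr[[nm("dec", l, "W2")]] <- r2$dw; gr[[nm("dec", l, "b2")]] <- r2$db
    r1 <- conv_act_bwd(lev$c1, params[[nm("dec", l, "W1")]], r2$dx, act)
    gr[[nm("dec", l, "W1")]] <- r1$dw; gr[[nm("dec", l, "b1")]] <- r1$db
    pieces <- split_channels(r1$dx, lev$cs)
    dup <- pieces[[1]]
    dsk <- NULL
    i <- 2L
    skip <- cache$enc[[l]]$skip
    if (use_att) {
      gb <- gate_bwd(pieces[[i]], skip, lev$up,
                     params[[nm("att", l, "Wx")]],
                     params[[nm("att", l, "Wg")]],
                     params[[nm("att", l, "Ws")]], lev$gate)
      i <- i + 1L
      dsk <- gb$dx
      dup <- dup + gb$dg
      gr[[nm("att", l, "Wx")]] <- gb$dWx
      gr[[nm("att", l, "Wg")]] <- gb$dWg
      gr[[nm("att", l, "Ws")]] <- gb$dWs
    }
    if (use_sharp) {
      ds <- if (isTRUE(lev$sharp_applied)) nn_sharpen_bwd(pieces[[i]], K)
            else pieces[[i]]
      i <- i + 1L
      dsk <- if (is.null(dsk)) ds else dsk + ds
    }
    if (!use_att && !use_sharp) dsk <- pieces[[2]]
    dskip[[l]] <- dsk
    ru <- nn_tconv_bwd(lev$up_in, params[[nm("dec", l, "Wu")]], dup)
    gr[[nm("dec", l, "Wu")]] <- ru$dw; gr[[nm("dec", l, "bu")]] <- ru$db
    dh <- ru$dx
  }
  bot <- cache$bot
  if (!is.null(bot$mask)) dh <- dh * bot$mask
  r2 <- conv_act_bwd(bot$c2, params[["bot.W2"]], dh, act)
  gr[["bot.W2"]] <- r2$dw; gr[["bot.b2"]] <- r2$db
  r1 <- conv_act_bwd(bot$c1, params[["bot.W1"]], r2$dx, act)
  gr[["bot.W1"]] <- r1$dw; gr[["bot.b1"]] <- r1$db
  dh <- r1$dx
  for (l in rev(seq_len(dep))) {
    lev <- cache$enc[[l]]
    dpool <- nn_maxpool_bwd(lev$mpidx, dh)
    d <- dpool + dskip[[l]]
    if (!is.null(lev$mask)) d <- d * lev$mask
    r2 <- conv_act_bwd(lev$c2, params[[nm("enc", l, "W2")]], d, act)
    gr[[nm("enc", l, "W2")]] <- r2$dw; gr[[nm("enc", l, "b2")]] <- r2$db
    r1 <- conv_act_bwd(lev$c1, params[[nm("enc", l, "W1")]], r2$dx, act)
    gr[[nm("enc", l, "W1")]] <- r1$dw; gr[[nm("enc", l, "b1")]] <- r1$db
    dh <- r1$dx
  }
  gr
}

#' Run inference on a batch of images
#'
#' Dropout is disabled, so the output is deterministic for fixed weights.
#'
#' @param model a `sharpseg_model`.
#' @param x numeric array (H, W, 1, B) of inputs scaled to [0, 1], or a
#'   single H x W matrix.
#' @param batch_size forward chunk size.
#' @return probability array (H, W, 1, B) with values in (0, 1).
#' @export
predict_probs <- function(model, x, batch_size = 16L) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  B <- dim(x)[4]
  out <- array(0, c(dim(x)[1:2], 1L, B))
  for (at in seq(1, B, by = batch_size)) {
    sel <- at:min(at + batch_size - 1, B)
    xb <- x[, , , sel, drop = FALSE]
    out[, , , sel] <- net_forward(model$params, model$spec, xb,
                                  train = FALSE)$p
  }
  out
}
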