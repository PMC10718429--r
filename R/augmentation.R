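#' Training-time augmentation configuration
#'
#' Parameter ranges for stochastic affine augmentation of image/mask pairs:
#' rotation in [-45, 45] degrees, zoom in [-0.08, 0.08] (applied as scale
#' factor `1 + z`), horizontal flip enabled, width/height shift fractions of
#' 0.15, shear in [-0.03, 0.03] (radians, along x), and multiplicative
#' brightness in [0.99, 1.07] (image only). Each draw is uniform over its
#' interval; the flip is a fair coin when enabled.
#'
#' @param rotation_deg,zoom,shear,brightness length-2 numeric intervals.
#' @param horizontal_flip logical.
#' @param width_shift_frac,height_shift_frac maximal absolute shift as a
#'   fraction of width/height; the shift is drawn from `[-f, f]`.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_deg = c(-45, 45),
                                zoom = c(-0.08, 0.08),
                                horizontal_flip = TRUE,
                                width_shift_frac = 0.15,
                                height_shift_frac = 0.15,
                                shear = c(-0.03, 0.03),
                                brightness = c(0.99, 1.07)) {
  chk <- function(iv, nm) {
    if (length(iv) != 2 || iv[1] > iv[2]) stop(nm, " must be a valid interval")
  }
  chk(rotation_deg, "rotation_deg"); chk(zoom, "zoom")
  chk(shear, "shear"); chk(brightness, "brightness")
  if (width_shift_frac < 0 || width_shift_frac > 1 ||
      height_shift_frac < 0 || height_shift_frac > 1)
    stop("shift fractions must lie in [0, 1]")
  structure(list(rotation_deg = rotation_deg, zoom = zoom,
                 horizontal_flip = isTRUE(horizontal_flip),
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 shear = shear, brightness = brightness),
            class = "augmentation_config")
}

#' Draw one set of transform parameters
#'
#' Uses the current RNG state (seed upstream for reproducibility): each
#' parameter uniform over its configured interval, flip a fair coin when
#' enabled.
#'
#' @param config an [augmentation_config()].
#' @return list with `angle`, `zoom_factor`, `flip`, `dx`, `dy`,
#'   `shear_amount`, `brightness_factor`.
#' @export
sample_transform <- function(config = augmentation_config()) {
  u <- function(iv) runif(1, iv[1], iv[2])
  list(
    angle = u(config$rotation_deg),
    zoom_factor = u(config$zoom),
    flip = config$horizontal_flip && runif(1) < 0.5,
    dx = runif(1, -config$width_shift_frac, config$width_shift_frac),
    dy = runif(1, -config$height_shift_frac, config$height_shift_frac),
    shear_amount = u(config$shear),
    brightness_factor = u(config$brightness)
  )
}

identity_transform <- function() {
  list(angle = 0, zoom_factor = 0, flip = FALSE, dx = 0, dy = 0,
       shear_amount = 0, brightness_factor = 1)
}

#' Apply one augmentation transform to an image/mask pair
#'
#' A single affine warp -- rotation o shear o zoom o shift about the image
#' centre, then an optional horizontal flip -- is applied identically to the
#' image and the mask, so they stay aligned. Sampling is bilinear by inverse
#' mapping; out-of-bounds image samples replicate the nearest edge while
#' mask samples are zero (no lesion is invented). The mask is re-binarized
#' at 0.5 after warping. Brightness multiplies the image only, with the
#' result rounded and clipped to [0, 255].
#'
#' @param image intensity matrix (0-255).
#' @param mask binary matrix of the same size (or NULL).
#' @param params transform parameters from [sample_transform()].
#' @return list with warped `image` and `mask`.
#' @export
apply_transform <- function(image, mask = NULL, params) {
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  h <- nrow(image); w <- ncol(image)
  th <- params$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, params$shear_amount, 1), 2, 2)
  Z <- diag(2) * (1 + params$zoom_factor)
  A <- R %*% Sh %*% Z                       # forward linear part
  t <- c(params$dx * w, params$dy * h)      # shift applied first (in src)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  Ainv <- solve(A)
  # destination pixel grid, 0-based (x = col, y = row)
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  if (isTRUE(params$flip)) xs <- (w - 1) - xs
  src <- Ainv %*% rbind(xs - cx, ys - cy)
  sx <- src[1, ] + cx - t[1]
  sy <- src[2, ] + cy - t[2]
  out_img <- matrix(sample_bilinear(image, sy, sx, fill = "edge"), h, w)
  out_img <- round(pmin(pmax(out_img * params$brightness_factor, 0), 255))
  storage.mode(out_img) <- "integer"
  out_msk <- NULL
  if (!is.null(mask)) {
    out_msk <- matrix(sample_bilinear(mask, sy, sx, fill = "zero"), h, w)
    out_msk <- matrix(as.integer(out_msk >= 0.5), h, w)
  }
  list(image = out_img, mask = out_msk)
}

# bilinear sampling at fractional (row, col) 0-based coordinates
sample_bilinear <- function(m, sy, sx, fill = c("edge", "zero")) {
  fill <- match.arg(fill)
  h <- nrow(m); w <- ncol(m)
  inside <- sy >= 0 & sy <= h - 1 & sx >= 0 & sx <= w - 1
  cy <- pmin(pmax(sy, 0), h - 1)
  cx <- pmin(pmax(sx, 0), w - 1)
  y0 <- floor(cy); x0 <- floor(cx)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- cy - y0; fx <- cx - x0
  m <- as.numeric(m); dim(m) <- c(h, w)
  v <- m[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
       m[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
       m[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
       m[cbind(y1 + 1, x1 + 1)] * fy * fx
  if (fill == "zero") v[!inside] <- 0
  v
}
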