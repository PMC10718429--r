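#' Configuration for one synthetic ultrasound phantom
#'
#' Phantoms emulate B-mode breast ultrasound: a multiplicative speckle
#' background (squared magnitude of a smoothed complex Gaussian field, a
#' Rayleigh-like envelope), and -- for benign/malignant labels -- a darker
#' (hypoechoic) elliptical lesion whose boundary is radially perturbed by a
#' smooth low-order harmonic function. Benign lesions are smooth
#' (`boundary_irregularity = 0`); malignant ones are spiculated. An optional
#' posterior shadow darkens the column band below the lesion. The mask is
#' the analytic lesion support itself, so ground truth is exact.
#'
#' @param side image side in pixels (square phantom).
#' @param label `"normal"`, `"benign"` or `"malignant"`.
#' @param background_mean mean background intensity (default 140).
#' @param speckle_scale speckle grain correlation length in pixels
#'   (Gaussian smoothing sigma of the complex field, default 1.5).
#' @param lesion_radius_frac interval of lesion semi-axes as a fraction of
#'   `side` (default c(0.12, 0.26)).
#' @param lesion_contrast multiplicative intensity factor inside the lesion,
#'   in (0, 1) (default 0.45).
#' @param boundary_irregularity radial perturbation amplitude; 0 for benign,
#'   default 0.25 for malignant.
#' @param shadow_strength posterior shadow attenuation in [0, 1]
#'   (default 0.2).
#' @param seed integer seed; the phantom is a pure function of its config.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(side = 128,
                           label = c("benign", "malignant", "normal"),
                           background_mean = 140, speckle_scale = 1.5,
                           lesion_radius_frac = c(0.12, 0.26),
                           lesion_contrast = 0.45,
                           boundary_irregularity = NULL,
                           shadow_strength = 0.2, seed = 1L) {
  label <- match.arg(label)
  if (lesion_contrast <= 0 || lesion_contrast >= 1)
    stop("lesion_contrast must lie in (0, 1)")
  if (is.null(boundary_irregularity))
    boundary_irregularity <- if (label == "malignant") 0.25 else 0
  if (boundary_irregularity < 0) stop("boundary_irregularity must be >= 0")
  structure(list(side = as.integer(side), label = label,
                 background_mean = background_mean,
                 speckle_scale = speckle_scale,
                 lesion_radius_frac = lesion_radius_frac,
                 lesion_contrast = lesion_contrast,
                 boundary_irregularity = boundary_irregularity,
                 shadow_strength = shadow_strength, seed = as.integer(seed)),
            class = "phantom_config")
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(2 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k, k)
  k / sum(k)
}

smooth2d <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  x <- array(m, c(dim(m), 1L, 1L))
  w <- array(k, c(dim(k), 1L, 1L))
  matrix(nn_conv_fwd(x, w, 0), nrow(m), ncol(m))
}

#' Generate one speckle phantom with its ground-truth mask
#'
#' @param cfg a [phantom_config()].
#' @return list with `image` (integer matrix 0-255), `mask` (binary
#'   matrix; all-zero for the normal class) and `label`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  s <- cfg$side
  with_seed(cfg$seed, {
    re <- smooth2d(matrix(rnorm(s * s), s, s), cfg$speckle_scale)
    im <- smooth2d(matrix(rnorm(s * s), s, s), cfg$speckle_scale)
    env <- re^2 + im^2
    img <- cfg$background_mean * env / mean(env)
    mask <- matrix(0L, s, s)
    if (cfg$label != "normal") {
      rf <- cfg$lesion_radius_frac
      a <- runif(1, rf[1], rf[2]) * s
      b <- runif(1, rf[1], rf[2]) * s
      if (2 * max(a, b) * (1 + cfg$boundary_irregularity) > s)
        stop("lesion larger than image")
      cx <- runif(1, 0.35, 0.65) * s
      cy <- runif(1, 0.35, 0.65) * s
      phi <- runif(1, 0, pi)
      nh <- 3:8
      amp <- rnorm(length(nh)) / nh
      pha <- runif(length(nh), 0, 2 * pi)
      amp <- amp / max(1e-9, sqrt(sum(amp^2) / 2))  # unit-RMS perturbation
      xs <- matrix(rep(seq_len(s) - 0.5, each = s), s, s) - cx   # col coord
      ys <- matrix(rep(seq_len(s) - 0.5, times = s), s, s) - cy  # row coord
      u <- cos(phi) * xs + sin(phi) * ys
      v <- -sin(phi) * xs + cos(phi) * ys
      rho <- sqrt((u / a)^2 + (v / b)^2)
      theta <- atan2(v / b, u / a)
      pert <- matrix(0, s, s)
      for (h in seq_along(nh))
        pert <- pert + amp[h] * cos(nh[h] * theta + pha[h])
      edge <- pmax(0.2, 1 + cfg$boundary_irregularity * pert)
      mask[rho <= edge] <- 1L
      img[mask == 1L] <- img[mask == 1L] * cfg$lesion_contrast
      if (cfg$shadow_strength > 0) {
        below <- matrix(rep(seq_len(s) - 0.5, times = s), s, s) >
          cy + 0.5 * b
        lateral <- exp(-(xs / a)^2)
        att <- 1 - cfg$shadow_strength * lateral * below
        img <- img * att
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    list(image = img, mask = mask, label = cfg$label)
  })
}

#' Generate a BUSI-style phantom dataset on disk
#'
#' Writes `n_per_class` phantoms per class as PNG image/mask pairs under
#' `out_root/{normal,benign,malignant}/<stem>.png` + `<stem>_mask.png`,
#' consumable by [scan_busi_layout()]. Per-item seeds are derived
#' deterministically from `base_seed`, so two runs produce byte-identical
#' files. Image sides are cycled deterministically through `sides` to
#' exercise the resize path.
#'
#' @param n_per_class named or positional counts for
#'   (normal, benign, malignant).
#' @param out_root output directory (created if missing).
#' @param base_seed integer seed.
#' @param sides integer vector of candidate image sides (default a small
#'   set around the 500-600 px scale of clinical exports).
#' @param ... further arguments passed to [phantom_config()] (e.g.
#'   `lesion_contrast`).
#' @return record `data.frame` as returned by [scan_busi_layout()].
#' @export
generate_dataset <- function(n_per_class, out_root, base_seed = 1L,
                             sides = c(480L, 512L, 544L, 576L, 608L), ...) {
  if (length(n_per_class) != 3) stop("n_per_class must have three counts")
  classes <- c("normal", "benign", "malignant")
  if (!is.null(names(n_per_class))) n_per_class <- n_per_class[classes]
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  idx <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    d <- file.path(out_root, cl)
    dir.create(d, showWarnings = FALSE)
    for (i in seq_len(n_per_class[[ci]])) {
      idx <- idx + 1L
      seed_i <- (as.integer(base_seed) + 7919L * idx) %% .Machine$integer.max
      side <- sides[(idx - 1L) %% length(sides) + 1L]
      ph <- generate_phantom(phantom_config(side = side, label = cl,
                                            seed = seed_i, ...))
      stem <- sprintf("%s_%03d", cl, i)
      write_image(ph$image, file.path(d, paste0(stem, ".png")))
      write_mask(ph$mask, file.path(d, paste0(stem, "_mask.png")))
    }
  }
  scan_busi_layout(out_root)
}
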