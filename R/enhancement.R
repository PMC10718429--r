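#' CLAHE configuration
#'
#' Contrast-limited adaptive histogram equalization operates on a grid of
#' `tile_rows x tile_cols` image tiles with `n_gray` histogram bins. The
#' per-tile clip limit is `clip_limit(M, N, alpha, s_max)` where `M` is the
#' tile pixel count; larger `clip_factor` (alpha, in percent) or `s_max`
#' (maximum tolerable slope of the mapping) allow stronger local contrast
#' amplification.
#'
#' @param tile_rows,tile_cols tile grid (default 8 x 8).
#' @param n_gray number of gray levels N (default 256).
#' @param clip_factor clip factor alpha in percent (default 100).
#' @param s_max maximum tolerable slope (default 4): the defaults give a
#'   clip limit of four times the uniform bin count.
#' @return a `clahe_config` list.
#' @export
clahe_config <- function(tile_rows = 8, tile_cols = 8, n_gray = 256,
                         clip_factor = 100, s_max = 4) {
  if (tile_rows < 1 || tile_cols < 1) stop("tile grid must be >= 1 x 1")
  if (n_gray < 2) stop("n_gray must be >= 2")
  if (clip_factor < 0) stop("clip_factor must be >= 0")
  if (s_max < 1) stop("s_max must be >= 1")
  structure(list(tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 n_gray = as.integer(n_gray),
                 clip_factor = clip_factor, s_max = s_max),
            class = "clahe_config")
}

#' Histogram clip limit
#'
#' The contrast constraint of CLAHE:
#' `beta = (M / N) * (1 + (alpha / 100) * (s_max - 1))`,
#' where `M` is the tile area in pixels, `N` the number of gray levels,
#' `alpha` the clip factor in percent and `s_max` the maximum tolerable
#' slope. `alpha = 0` collapses to the uniform bin count `M / N`; the limit
#' is non-decreasing in each argument.
#'
#' @param M tile area in pixels (>= 1).
#' @param N number of gray levels (>= 2).
#' @param alpha clip factor in percent (>= 0).
#' @param s_max maximum tolerable slope (>= 1).
#' @return the clip limit beta (histogram counts; may be fractional).
#' @examples
#' clip_limit(64, 256, 0, 4)    # 0.25
#' clip_limit(64, 256, 100, 4)  # 1
#' @export
clip_limit <- function(M, N, alpha, s_max) {
  if (any(M < 1) || any(N < 2)) stop("M must be >= 1 and N >= 2")
  if (any(alpha < 0) || any(s_max < 1)) stop("alpha >= 0 and s_max >= 1 required")
  (M / N) * (1 + (alpha / 100) * (s_max - 1))
}

#' Apply CLAHE to a grayscale image
#'
#' Per tile, the intensity histogram (N bins) is clipped at the limit from
#' [clip_limit()] and the excess redistributed uniformly over all bins in a
#' single pass; the equalization mapping of each tile is the normalized
#' cumulative histogram rescaled so the lowest occupied level maps to 0 and
#' the top to `N - 1`. Each pixel's output blends the mappings of its four
#' neighbouring tile centres by bilinear interpolation; border pixels clamp
#' to the edge tiles. The transform is deterministic and, within any one
#' tile, monotone non-decreasing in input intensity.
#'
#' @param image integer matrix of intensities 0-255.
#' @param config a [clahe_config()].
#' @return integer matrix of the same size, values in `0 .. n_gray - 1`.
#' @export
apply_clahe <- function(image, config = clahe_config()) {
  stopifnot(inherits(config, "clahe_config"))
  h <- nrow(image); w <- ncol(image)
  tr <- config$tile_rows; tc <- config$tile_cols
  if (tr > h || tc > w) stop("tile grid larger than image")
  N <- config$n_gray
  # bin index per pixel, 0-based
  bins <- pmin(floor(image / 256 * N), N - 1)
  rb <- floor(seq(0, h, length.out = tr + 1))  # tile row breaks, 0-based
  cb <- floor(seq(0, w, length.out = tc + 1))
  luts <- array(0, c(tr, tc, N))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (ti in seq_len(tr)) {
    centers_r[ti] <- (rb[ti] + rb[ti + 1]) / 2 - 0.5
    for (tj in seq_len(tc)) {
      centers_c[tj] <- (cb[tj] + cb[tj + 1]) / 2 - 0.5
      px <- bins[(rb[ti] + 1):rb[ti + 1], (cb[tj] + 1):cb[tj + 1]]
      M <- length(px)
      hist <- tabulate(px + 1L, nbins = N)
      beta <- clip_limit(M, N, config$clip_factor, config$s_max)
      clipped <- pmin(hist, beta)
      excess <- M - sum(clipped)
      h2 <- clipped + excess / N
      cdf <- cumsum(h2) / M
      occ <- which(h2 > 0)
      fmin <- cdf[occ[1]]
      if (1 - fmin < 1e-12) {
        # single occupied level: identity mapping (constant tiles unchanged)
        luts[ti, tj, ] <- seq_len(N) - 1
      } else {
        luts[ti, tj, ] <- (N - 1) * pmax(cdf - fmin, 0) / (1 - fmin)
      }
    }
  }
  # bilinear blend of the four neighbouring tile mappings
  pos_r <- interp_axis(seq_len(h) - 1, centers_r)
  pos_c <- interp_axis(seq_len(w) - 1, centers_c)
  bin1 <- bins + 1L
  out <- matrix(0, h, w)
  tlo_r <- pos_r$lo; thi_r <- pos_r$hi; wr <- pos_r$w
  tlo_c <- pos_c$lo; thi_c <- pos_c$hi; wc <- pos_c$w
  for (tj in seq_len(tc)) {
    colsel <- which(tlo_c == tj | thi_c == tj)
    if (length(colsel) == 0) next
    for (ti in seq_len(tr)) {
      rowsel <- which(tlo_r == ti | thi_r == ti)
      if (length(rowsel) == 0) next
      # weight of tile (ti, tj) at each (row, col) in the selection
      wrr <- ifelse(tlo_r[rowsel] == ti, 1 - wr[rowsel], 0) +
             ifelse(thi_r[rowsel] == ti & thi_r[rowsel] != tlo_r[rowsel],
                    wr[rowsel], 0)
      wcc <- ifelse(tlo_c[colsel] == tj, 1 - wc[colsel], 0) +
             ifelse(thi_c[colsel] == tj & thi_c[colsel] != tlo_c[colsel],
                    wc[colsel], 0)
      lut <- luts[ti, tj, ]
      vals <- matrix(lut[bin1[rowsel, colsel]], length(rowsel), length(colsel))
      out[rowsel, colsel] <- out[rowsel, colsel] +
        (outer(wrr, wcc)) * vals
    }
  }
  out <- round(pmin(pmax(out, 0), N - 1))
  storage.mode(out) <- "integer"
  out
}

# For each 0-based coordinate, the bracketing tile indices (1-based) along
# one axis and the interpolation weight toward the upper tile; coordinates
# outside the span of tile centres clamp to the edge tile.
interp_axis <- function(coord, centers) {
  nt <- length(centers)
  lo <- findInterval(coord, centers)
  hi <- pmin(lo + 1, nt)
  lo <- pmax(lo, 1)
  w <- rep(0, length(coord))
  inner <- which(hi > lo)
  if (length(inner)) {
    w[inner] <- (coord[inner] - centers[lo[inner]]) /
      (centers[hi[inner]] - centers[lo[inner]])
  }
  before <- coord < centers[1]
  w[before] <- 0; hi[before] <- 1; lo[before] <- 1
  after <- coord >= centers[nt]
  w[after] <- 0; lo[after] <- nt; hi[after] <- nt
  list(lo = lo, hi = hi, w = w)
}
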