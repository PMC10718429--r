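#' Read a grayscale image as an intensity matrix
#'
#' Reads a PNG and returns an integer matrix of 8-bit intensities (0-255),
#' rows indexed from the top. Multi-channel images are collapsed to
#' luminance (Rec. 601 weights 0.299/0.587/0.114); an alpha channel, if
#' present, is ignored.
#'
#' @param path path to a PNG file.
#' @return integer matrix (height x width) with values in 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop("not a readable PNG: ", path))
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]  # gray + alpha
    }
  }
  m <- round(arr * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param image numeric/integer matrix with values in 0-255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (any(image < 0 | image > 255)) stop("intensities must lie in [0, 255]")
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a PNG and binarizes at `> 0`: any nonzero intensity marks lesion.
#'
#' @param path path to a PNG mask file.
#' @return integer matrix of \{0, 1\}.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  m[] <- as.integer(m > 0)
  m
}

#' Write a binary mask as PNG (0/255)
#'
#' @param mask matrix of \{0, 1\}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  write_image(mask * 255L, path)
}

#' Load and merge the mask(s) of one dataset record
#'
#' BUSI-style layouts can carry several mask files for one image (multiple
#' outlined lesions); they are merged by pixel-wise OR.
#'
#' @param mask_path one path, or several joined by `";"` as stored by
#'   [scan_busi_layout()].
#' @return integer matrix of \{0, 1\}.
#' @export
load_record_mask <- function(mask_path) {
  paths <- strsplit(mask_path, ";", fixed = TRUE)[[1]]
  m <- read_mask(paths[[1]])
  for (p in paths[-1]) {
    m2 <- read_mask(p)
    if (!identical(dim(m), dim(m2)))
      stop("mask dimension mismatch among: ", mask_path)
    m <- pmax(m, m2)
  }
  m
}

#' Scan a BUSI-style directory layout into dataset records
#'
#' Expects `root/{normal,benign,malignant}/<stem>.png` with masks named
#' `<stem>_mask.png` (and optionally `<stem>_mask_1.png`, ...). Class labels
#' come from the folder names. Images lacking any mask file raise an error
#' naming the stem; multiple masks are recorded together and merged by OR
#' when loaded.
#'
#' @param root dataset root directory.
#' @return `data.frame` with columns `image_path`, `mask_path`
#'   (";"-separated when multiple) and `label`.
#' @export
scan_busi_layout <- function(root) {
  classes <- c("normal", "benign", "malignant")
  recs <- list()
  for (cl in classes) {
    d <- file.path(root, cl)
    if (!dir.exists(d)) next
    files <- sort(list.files(d, pattern = "\\.png$", full.names = FALSE))
    is_mask <- grepl("_mask(_[0-9]+)?\\.png$", files)
    imgs <- files[!is_mask]
    for (f in imgs) {
      stem <- sub("\\.png$", "", f)
      mpat <- paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", stem),
                     "_mask(_[0-9]+)?\\.png$")
      masks <- files[grepl(mpat, files)]
      if (length(masks) == 0)
        stop("image without mask file: ", file.path(cl, stem))
      recs[[length(recs) + 1L]] <- data.frame(
        image_path = file.path(d, f),
        mask_path = paste(file.path(d, masks), collapse = ";"),
        label = cl,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(recs) == 0) {
    return(data.frame(image_path = character(), mask_path = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Randomly partition records into train/validation/test
#'
#' One seeded shuffle followed by floor cuts at `n * r_train` and
#' `n * (r_train + r_val)`; no class stratification. With 780 records and
#' the default ratios this yields 624/78/78.
#'
#' @param records `data.frame` of dataset records.
#' @param ratios length-3 numeric summing to 1.
#' @param seed integer RNG seed; the split is deterministic given the seed.
#' @return list with elements `train`, `validation`, `test` (record
#'   data.frames) and `seed`.
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three numbers summing to 1")
  n <- nrow(records)
  if (n < 3) stop("need at least 3 records to populate all splits")
  ord <- with_seed(seed, sample.int(n))
  c1 <- floor(n * ratios[1])
  c2 <- floor(n * (ratios[1] + ratios[2]))
  list(
    train = records[ord[seq_len(c1)], , drop = FALSE],
    validation = records[ord[c1 + seq_len(c2 - c1)], , drop = FALSE],
    test = records[ord[c2 + seq_len(n - c2)], , drop = FALSE],
    seed = as.integer(seed)
  )
}

#' Write a split manifest as CSV
#'
#' @param split result of [split_dataset()].
#' @param path output CSV path with columns
#'   `path, mask_path, label, split`.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  rows <- lapply(c("train", "validation", "test"), function(s) {
    r <- split[[s]]
    if (nrow(r) == 0) return(NULL)
    data.frame(path = r$image_path, mask_path = r$mask_path,
               label = r$label, split = s, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Resize an image/mask pair to a square side
#'
#' The image is resampled with bilinear interpolation, the mask with
#' nearest-neighbour sampling at pixel centres and re-binarized, so labels
#' stay strictly binary.
#'
#' @param image intensity matrix.
#' @param mask binary matrix of the same dimensions (or NULL).
#' @param side positive integer output side.
#' @return list with `image` and `mask` resized to `side x side`.
#' @export
resize_pair <- function(image, mask = NULL, side) {
  if (side <= 0) stop("side must be positive")
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  img <- resize_bilinear(image, side, side)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  msk <- NULL
  if (!is.null(mask)) {
    msk <- resize_nearest(mask, side, side)
    msk[] <- as.integer(msk > 0)
  }
  list(image = img, mask = msk)
}

# nearest-neighbour: destination pixel centre (i + 0.5) maps to source index
# floor((i + 0.5) * scale)
resize_nearest <- function(m, ho, wo) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(floor((seq_len(ho) - 0.5) * h / ho) + 1, h)
  ci <- pmin(floor((seq_len(wo) - 0.5) * w / wo) + 1, w)
  m[ri, ci, drop = FALSE]
}

resize_bilinear <- function(m, ho, wo) {
  h <- nrow(m); w <- ncol(m)
  u <- pmin(pmax((seq_len(ho) - 0.5) * h / ho - 0.5, 0), h - 1)
  v <- pmin(pmax((seq_len(wo) - 0.5) * w / wo - 0.5, 0), w - 1)
  u0 <- floor(u); v0 <- floor(v)
  u1 <- pmin(u0 + 1, h - 1); v1 <- pmin(v0 + 1, w - 1)
  fu <- u - u0; fv <- v - v0
  m <- matrix(as.numeric(m), h, w)
  a <- m[u0 + 1, v0 + 1, drop = FALSE]
  b <- m[u1 + 1, v0 + 1, drop = FALSE]
  cc <- m[u0 + 1, v1 + 1, drop = FALSE]
  d <- m[u1 + 1, v1 + 1, drop = FALSE]
  wu <- matrix(fu, ho, wo)
  wv <- matrix(fv, ho, wo, byrow = TRUE)
  a * (1 - wu) * (1 - wv) + b * wu * (1 - wv) +
    cc * (1 - wu) * wv + d * wu * wv
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
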