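# In-code fixtures shared across tests: tiny images, masks and tensors.

rand_tensor <- function(h, w, c, b, sd = 1) {
  array(rnorm(h * w * c * b, sd = sd), c(h, w, c, b))
}

# brute-force depthwise 2-D sliding-window correlation with edge-replicate
# padding; the independent oracle for the compiled sharpening op
sharpen_oracle <- function(x, k) {
  d <- dim(x)
  out <- array(0, d)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  for (b in seq_len(d[4])) for (cc in seq_len(d[3])) {
    m <- array(x[, , cc, b], d[1:2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        acc <- acc + k[di + 2, dj + 2] *
          m[clamp(i + di, 1, d[1]), clamp(j + dj, 1, d[2])]
      }
      out[i, j, cc, b] <- acc
    }
  }
  out
}

# small phantom dataset on disk, cached per test session
tiny_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "sharpseg-tiny-data")
      if (!dir.exists(dir))
        generate_dataset(c(2, 3, 2), dir, base_seed = 404,
                         sides = c(40L, 48L))
    }
    dir
  }
})
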