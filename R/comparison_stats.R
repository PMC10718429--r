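#' Pixel-wise discordance counts between two models
#'
#' For every pixel of every test image, each model's prediction is scored
#' correct or wrong against the ground truth; `b` counts pixels where model
#' A is correct and model B wrong, `c` the reverse. Counts are pooled across
#' all images of the test set.
#'
#' @param predA,predB lists of binary prediction matrices (or single
#'   matrices/arrays), aligned with `truth`.
#' @param truth list of binary ground-truth matrices (same shapes).
#' @return list with `b`, `c`, `n_images`, `n_pixels`.
#' @export
discordant_counts <- function(predA, predB, truth) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  predA <- as_list(predA); predB <- as_list(predB); truth <- as_list(truth)
  if (length(predA) != length(truth) || length(predB) != length(truth))
    stop("prediction and truth collections differ in length")
  b <- 0; cc <- 0; np <- 0
  for (i in seq_along(truth)) {
    y <- truth[[i]]; a <- predA[[i]]; bb <- predB[[i]]
    if (!identical(dim(y) %||% length(y), dim(a) %||% length(a)) ||
        !identical(dim(y) %||% length(y), dim(bb) %||% length(bb)))
      stop("shape mismatch at image ", i)
    okA <- a == y; okB <- bb == y
    b <- b + sum(okA & !okB)
    cc <- cc + sum(!okA & okB)
    np <- np + length(y)
  }
  list(b = b, c = cc, n_images = length(truth), n_pixels = np)
}

#' McNemar's test on discordance counts
#'
#' The test statistic is `(b - c)^2 / (b + c)`, referred to the chi-squared
#' distribution with 1 degree of freedom (upper tail), without continuity
#' correction. When `b + c = 0` the models never disagree and `p = 1` by
#' convention. An exact binomial version (`exact = TRUE`) is available for
#' small discordance counts: `p = min(1, 2 * P[Binom(b + c, 1/2) <= min(b, c)])`.
#'
#' @param counts list with `b` and `c` (e.g. from [discordant_counts()]).
#' @param exact use the exact binomial test instead of the chi-squared
#'   approximation.
#' @return list with `statistic`, `p_raw`, `b`, `c`.
#' @examples
#' mcnemar_test(list(b = 8, c = 2))  # statistic 3.6, p ~ 0.0578
#' @export
mcnemar_test <- function(counts, exact = FALSE) {
  b <- counts$b; cc <- counts$c
  if (b < 0 || cc < 0) stop("counts must be non-negative")
  if (b + cc == 0)
    return(list(statistic = 0, p_raw = 1, b = b, c = cc))
  stat <- (b - cc)^2 / (b + cc)
  p <- if (exact) {
    min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  } else {
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_raw = p, b = b, c = cc)
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of simultaneous tests `m` and
#' capped at 1; the adjustment preserves the ordering of the raw values.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @param m number of tests (defaults to `length(p_values)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must cover all tests")
  pmin(1, m * p_values)
}

#' Pairwise McNemar comparison of segmentation models
#'
#' Runs the pixel-wise McNemar test for every pair of models against a
#' shared ground truth, Bonferroni-adjusting over the number of pairs. With
#' a family alpha of 0.1 the per-test cutoff is `0.1 / choose(k, 2)`; a pair
#' is flagged significant when its adjusted p-value falls below the family
#' alpha (equivalently, raw p below the per-test cutoff).
#'
#' @param predictions named list (>= 2 entries) mapping model name to a
#'   list of binary prediction matrices.
#' @param truth list of binary ground-truth matrices.
#' @param alpha_family family-wise alpha (default 0.1).
#' @param exact passed to [mcnemar_test()].
#' @return object of class `model_comparison`: list with `p_adjusted`
#'   (lower-triangular matrix), `results` (per-pair test details),
#'   `m`, `alpha_family`, `per_test_cutoff`.
#' @export
compare_models <- function(predictions, truth, alpha_family = 0.1,
                           exact = FALSE) {
  k <- length(predictions)
  if (k < 2) stop("need at least two models to compare")
  nms <- names(predictions)
  if (is.null(nms) || any(nms == "")) stop("predictions must be named")
  m <- choose(k, 2)
  pm <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  results <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      cnt <- discordant_counts(predictions[[i]], predictions[[j]], truth)
      tst <- mcnemar_test(cnt, exact = exact)
      tst$p_adjusted <- bonferroni_adjust(tst$p_raw, m)
      tst$significant <- tst$p_adjusted < alpha_family
      tst$models <- c(nms[i], nms[j])
      tst$n_images <- cnt$n_images
      results[[paste(nms[i], nms[j], sep = " vs ")]] <- tst
      pm[j, i] <- tst$p_adjusted
    }
  }
  structure(list(p_adjusted = pm, results = results, m = m,
                 alpha_family = alpha_family,
                 per_test_cutoff = alpha_family / m),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "Pairwise pixel-wise McNemar tests (%d pairs, Bonferroni, family alpha %.2g,\nper-test cutoff %.4g). Adjusted p-values:\n",
    x$m, x$alpha_family, x$per_test_cutoff))
  print(round(x$p_adjusted, 4), na.print = "")
  invisible(x)
}
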