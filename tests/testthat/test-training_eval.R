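# small in-memory dataset used across the training tests
make_tiny_data <- function(n, side = 16, seed = 123) {
  x <- array(0, c(side, side, 1, n))
  y <- array(0, c(side, side, 1, n))
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_config(side = side, label = "benign",
                                          seed = seed + i,
                                          lesion_radius_frac = c(0.2, 0.3),
                                          shadow_strength = 0))
    x[, , 1, i] <- ph$image
    y[, , 1, i] <- ph$mask
  }
  list(x = x, y = y)
}

test_that("binarize follows the >= threshold convention and is idempotent", {
  p <- array(0.39, c(3, 3, 1, 1))
  expect_true(all(binarize(p, 0.4) == 0))
  p[] <- 0.40
  expect_true(all(binarize(p, 0.4) == 1))
  p <- array(c(0.2, 0.5), c(2, 1, 1, 1))
  expect_equal(as.vector(binarize(p, 0.4)), c(0L, 1L))
  mixed <- array(runif(16), c(4, 4, 1, 1))
  b1 <- binarize(mixed, 0.4)
  expect_identical(binarize(b1, 0.4), b1)
  expect_error(binarize(mixed, 1.2), "threshold")
  expect_error(binarize(mixed, 0), "threshold")
})

test_that("threshold derivation finds the separating point", {
  probs <- c(rep(0.9, 50), rep(0.1, 50))
  truth <- c(rep(1, 50), rep(0, 50))
  th <- derive_threshold(probs, truth)
  expect_gt(th, 0.1); expect_lte(th, 0.9)
  pb <- as.integer(probs >= th)
  cm <- confusion_metrics(truth, pb)
  expect_equal(cm$sensitivity, 1)   # TPR 1
  expect_equal(cm$specificity, 1)   # FPR 0
  expect_error(derive_threshold(runif(10), rep(1, 10)), "both classes")
})

test_that("threshold for overlapping Gaussians sits near the midpoint", {
  set.seed(55)
  pos <- pmin(pmax(rnorm(4000, 0.65, 0.1), 0), 1)
  neg <- pmin(pmax(rnorm(4000, 0.35, 0.1), 0), 1)
  probs <- c(pos, neg)
  truth <- c(rep(1, 4000), rep(0, 4000))
  th <- derive_threshold(probs, truth)
  # independent brute-force sweep maximizing TPR - FPR
  grid <- seq(0.01, 0.99, by = 0.002)
  youden <- sapply(grid, function(t) {
    mean(pos >= t) - mean(neg >= t)
  })
  th_brute <- grid[which.max(youden)]
  expect_equal(th, th_brute, tolerance = 0.03)
  expect_equal(th, 0.5, tolerance = 0.05)
})

test_that("evaluating an oracle model scores perfectly; trivial baselines", {
  set.seed(77)
  y <- array(rbinom(3 * 64, 1, 0.3), c(8, 8, 1, 3))
  rep <- metrics_report(y, y * 0.99 + 0.005, threshold = 0.4)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$dice_coefficient, 1)
  expect_equal(rep$accuracy, 1)

  rep0 <- metrics_report(y, array(0.01, dim(y)), threshold = 0.4)
  expect_equal(rep0$sensitivity, 0)
  expect_equal(rep0$specificity, 1)
})

test_that("evaluate_model equals confusion_metrics on its own binarized maps", {
  dat <- make_tiny_data(4)
  m <- build_model(model_spec("unet", depth = 2, base_filters = 2,
                              input_side = 16), seed = 8)
  rep <- evaluate_model(m, dat, threshold = 0.4)
  probs <- attr(rep, "probs")
  cm <- confusion_metrics(dat$y, binarize(probs, 0.4))
  expect_equal(rep$accuracy, cm$accuracy)
  expect_equal(rep$precision, cm$precision)
  expect_equal(rep$sensitivity, cm$sensitivity)
  expect_equal(rep$dice_coefficient, cm$dice)
  expect_equal(rep$jaccard, cm$jaccard)
  expect_error(evaluate_model(m, list(x = array(0, c(16, 16, 1, 0)),
                                      y = array(0, c(16, 16, 1, 0)))),
               "empty")
})

test_that("zero learning rate leaves the model unchanged", {
  dat <- make_tiny_data(6)
  spec <- model_spec("unet", depth = 2, base_filters = 2, input_side = 16,
                     dropout_encoder = 0, dropout_decoder = 0)
  m <- build_model(spec, seed = 4)
  before <- sharpseg:::soft_dice_set(m, dat$x / 255, dat$y)
  fit <- train_model(m, dat, dat,
                     training_config(epochs = 2, batch_size = 3,
                                     learning_rate = 0, seed = 1),
                     acfg = NULL)
  expect_equal(fit$history$val_dice, rep(before, 2), tolerance = 1e-12)
  expect_identical(fit$model$params, m$params)
})

test_that("training is deterministic given the seed", {
  dat <- make_tiny_data(6)
  spec <- model_spec("unet", depth = 2, base_filters = 2, input_side = 16)
  run1 <- train_model(build_model(spec, seed = 4), dat, dat,
                      training_config(epochs = 1, batch_size = 3, seed = 9),
                      augmentation_config())
  run2 <- train_model(build_model(spec, seed = 4), dat, dat,
                      training_config(epochs = 1, batch_size = 3, seed = 9),
                      augmentation_config())
  expect_identical(run1$history$train_loss, run2$history$train_loss)
  expect_identical(run1$model$params, run2$model$params)
})

test_that("best checkpoint dominates the final epoch on validation", {
  dat <- make_tiny_data(8)
  spec <- model_spec("unet", depth = 2, base_filters = 4, input_side = 16)
  fit <- train_model(build_model(spec, seed = 2), dat, dat,
                     training_config(epochs = 4, batch_size = 4, seed = 3),
                     acfg = NULL)
  expect_equal(fit$best_val_dice, max(fit$history$val_dice),
               tolerance = 1e-12)
  expect_gte(fit$best_val_dice,
             fit$history$val_dice[nrow(fit$history)])
  expect_error(train_model(fit$model,
                           list(x = array(0, c(16, 16, 1, 0)),
                                y = array(0, c(16, 16, 1, 0))),
                           dat, training_config(epochs = 1)),
               "empty training split")
})

test_that("prepare_arrays loads, enhances and resizes records", {
  root <- tiny_dataset_dir()
  recs <- scan_busi_layout(root)
  dat <- prepare_arrays(recs, 32, clahe = clahe_config(tile_rows = 4,
                                                       tile_cols = 4))
  expect_identical(dim(dat$x), c(32L, 32L, 1L, nrow(recs)))
  expect_true(all(dat$y %in% c(0, 1)))
  expect_true(all(dat$x >= 0 & dat$x <= 255))
  # normal records stay all-zero through the resize path
  nrm <- which(recs$label == "normal")
  expect_true(all(dat$y[, , , nrm] == 0))
})
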