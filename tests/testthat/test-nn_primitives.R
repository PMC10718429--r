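test_that("activation closed forms", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 * sigmoid(1), tolerance = 1e-12)
  expect_equal(swish(1), 0.7310586, tolerance = 1e-6)
  expect_equal(mish(0), 0)
  expect_equal(mish(1), tanh(log(1 + exp(1))), tolerance = 1e-12)
  expect_equal(mish(1), 0.8650984, tolerance = 1e-6)
  expect_equal(relu(-3), 0)
  expect_equal(relu(4), 4)
  expect_equal(leaky_relu(-3), -0.3)
  expect_equal(leaky_relu(5), 5)
})

test_that("sigmoid symmetry and saturation; swish/mish tails", {
  x <- seq(-30, 30, by = 0.37)
  expect_equal(sigmoid(x), 1 - sigmoid(-x), tolerance = 1e-12)
  expect_equal(swish(800) / 800, 1, tolerance = 1e-12)
  expect_equal(mish(-800), 0, tolerance = 1e-12)
  # no NaN/Inf in extreme tails
  expect_true(all(is.finite(c(sigmoid(c(-1e4, 1e4)), swish(c(-1e4, 1e4)),
                              mish(c(-1e4, 1e4))))))
})

test_that("swish and mish are non-monotonic with a unique negative minimum", {
  x <- seq(-8, 2, by = 1e-3)
  for (f in list(swish, mish)) {
    y <- f(x)
    i <- which.min(y)
    expect_lt(y[i], 0)              # dips below zero
    expect_gt(x[i], -8); expect_lt(x[i], 0)
    # strictly decreasing then increasing around the minimum => unique
    expect_true(all(diff(y[seq_len(i)]) <= 0))
    expect_true(all(diff(y[seq(i, length(y))]) >= 0))
  }
})

test_that("binary cross-entropy closed forms", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)),
               -(log(0.9) + log(0.9)) / 2, tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)), 0.10536, tolerance = 1e-4)
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)  # clamped perfection
  expect_error(bce_loss(c(1, 0), 0.5), "shape")
})

test_that("Dice coefficient and loss on the overlap toys", {
  y <- rep(1, 100); p <- rep(1, 100)
  expect_equal(dice_coefficient(y, p), 200 / (200 + 1e-5), tolerance = 1e-12)
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # 4 true pixels, 4 predicted, 2 overlapping
  y <- c(1, 1, 1, 1, 0, 0); p <- c(1, 1, 0, 0, 1, 1)
  expect_equal(dice_coefficient(y, p), 4 / (8 + 1e-5), tolerance = 1e-9)
  expect_equal(dice_coefficient(y, p), 0.5, tolerance = 1e-4)
  expect_equal(dice_loss(y, p), 0.5, tolerance = 1e-4)
  expect_lt(dice_loss(rep(1, 10), rep(1, 10)), 1e-5)
  expect_equal(dice_loss(c(1, 0), c(0, 1)), 1)
})

test_that("bce_dice_loss is exactly the sum of its parts", {
  lt <- bce_dice_loss(1, 0.5)
  expect_equal(lt$bce, log(2), tolerance = 1e-12)
  expect_equal(lt$dice_loss, 1 - 1 / (1.5 + 1e-5), tolerance = 1e-9)
  expect_equal(lt$total, 1.0265, tolerance = 1e-3)
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    lt <- bce_dice_loss(y, p)
    expect_identical(lt$total, lt$bce + lt$dice_loss)
    expect_gte(lt$total, lt$dice_loss)  # bce is non-negative
  }
})

test_that("confusion metrics from pooled counts", {
  y <- rbinom(50, 1, 0.5)
  cm <- confusion_metrics(y, y)
  expect_equal(cm$accuracy, 1); expect_equal(cm$precision, 1)
  expect_equal(cm$sensitivity, 1); expect_equal(cm$specificity, 1)
  expect_equal(cm$f1, 1); expect_equal(cm$jaccard, 1)

  y <- c(rep(1, 10), rep(0, 90))
  cm <- confusion_metrics(y, rep(0, 100))
  expect_equal(cm$sensitivity, 0)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 0.9)

  # TP=3 FP=1 FN=1 TN=95
  y <- c(rep(1, 4), rep(0, 96))
  p <- c(rep(1, 3), 0, 1, rep(0, 95))
  cm <- confusion_metrics(y, p)
  expect_equal(cm$precision, 0.75); expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$f1, 0.75); expect_equal(cm$jaccard, 0.6)

  # vacuous cases: empty truth predicted empty is perfect
  cm <- confusion_metrics(rep(0, 5), rep(0, 5))
  expect_equal(cm$precision, 1); expect_equal(cm$sensitivity, 1)
  expect_equal(cm$jaccard, 1)
  expect_error(confusion_metrics(c(1, 0), c(0.5, 0)), "binary")
})

test_that("Dice/Jaccard relation and hard-Dice consistency", {
  set.seed(8)
  for (i in 1:25) {
    y <- rbinom(200, 1, 0.3)
    p <- rbinom(200, 1, 0.3)
    cm <- confusion_metrics(y, p)
    d <- dice_coefficient(y, p)
    expect_equal(d, 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn + 1e-9),
                 tolerance = 1e-4)
    if (cm$tp + cm$fp + cm$fn > 0) {
      expect_equal(cm$jaccard, cm$dice / (2 - cm$dice), tolerance = 1e-9)
      expect_lte(cm$jaccard, cm$dice)
    }
  }
})

test_that("metrics_report has the nine evaluation columns", {
  set.seed(3)
  y <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  p <- array(runif(64), c(8, 8, 1, 1))
  rep <- metrics_report(y, p, threshold = 0.4)
  expect_named(rep, c("accuracy", "loss", "dice_loss", "precision", "f1",
                      "sensitivity", "specificity", "dice_coefficient",
                      "jaccard"))
  ratios <- rep[c("accuracy", "precision", "f1", "sensitivity",
                  "specificity", "dice_coefficient", "jaccard")]
  expect_true(all(ratios >= 0 & ratios <= 1))
})
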