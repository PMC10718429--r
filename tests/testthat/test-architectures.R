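test_that("sharpening kernel is DC-preserving and fixes constant maps", {
  k <- sharpening_kernel()
  expect_equal(sum(k), 1)
  expect_equal(k, matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3,
                         byrow = TRUE))
  x <- array(3.7, c(6, 7, 2, 1))
  expect_equal(sharpen_features(x), x, tolerance = 1e-12)
})

test_that("sharpening an impulse reproduces the kernel pattern", {
  x <- matrix(0, 5, 5); x[3, 3] <- 1
  y <- sharpen_features(x)
  expect_equal(y[2:4, 2:4], sharpening_kernel())
  expect_equal(sum(y), 1)  # kernel sums to one
})

test_that("sharpen_features matches a brute-force sliding-window oracle", {
  set.seed(77)
  k <- sharpening_kernel()
  for (i in 1:100) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    cc <- sample(1:8, 1); b <- sample(1:2, 1)
    x <- rand_tensor(h, w, cc, b)
    expect_equal(sharpen_features(x), sharpen_oracle(x, k), tolerance = 1e-6)
  }
  # row-ramp example against the same oracle, replicate border included:
  # interior of a linear ramp is Laplacian-free, so only the ends respond
  ramp <- matrix(0:4, 1, 5, byrow = TRUE)
  got <- sharpen_features(ramp)
  expect_equal(as.vector(got),
               as.vector(sharpen_oracle(array(ramp, c(1, 5, 1, 1)), k)))
  expect_equal(as.vector(got)[2:4], c(1, 2, 3))
})

test_that("attention gate: zero weights halve the input exactly", {
  x <- rand_tensor(4, 4, 3, 2)
  g <- rand_tensor(4, 4, 3, 2)
  params <- list(Wx = array(0, c(1, 1, 3, 2)), Wg = array(0, c(1, 1, 3, 2)),
                 Ws = array(0, c(1, 1, 2, 1)))
  out <- attention_gate(x, g, params)
  expect_equal(array(out, dim(x)), 0.5 * x, tolerance = 1e-12)
  expect_true(all(attr(out, "attention") == 0.5))
})

test_that("attention gate scalar toy matches the hand-evaluated chain", {
  out <- attention_gate(1, 1, list(Wx = 1, Wg = 1, Ws = 1))
  a <- sigmoid(swish(2))
  expect_equal(as.numeric(out), a, tolerance = 1e-12)
  expect_equal(as.numeric(out), 0.8534, tolerance = 1e-4)
})

test_that("attention coefficients always lie strictly inside (0, 1)", {
  set.seed(14)
  for (i in 1:10) {
    x <- rand_tensor(6, 6, 4, 2)
    g <- rand_tensor(6, 6, 4, 2)
    params <- list(Wx = array(rnorm(8), c(1, 1, 4, 2)),
                   Wg = array(rnorm(8), c(1, 1, 4, 2)),
                   Ws = array(rnorm(2), c(1, 1, 2, 1)))
    a <- attr(attention_gate(x, g, params), "attention")
    expect_true(all(a > 0 & a < 1))
  }
  expect_error(attention_gate(rand_tensor(4, 4, 1, 1),
                              rand_tensor(6, 6, 1, 1),
                              list(Wx = 1, Wg = 1, Ws = 1)),
               "aligned")
})

test_that("all four variants emit probability maps shaped like the input", {
  set.seed(2)
  for (v in c("unet", "sharp", "attention", "sharp_attention")) {
    for (side in c(32L, 64L, 128L)) {
      m <- build_model(model_spec(v, base_filters = 4, input_side = side),
                       seed = 5)
      x <- array(runif(side * side * 2), c(side, side, 1, 2))
      p <- predict_probs(m, x)
      expect_identical(dim(p), c(side, side, 1L, 2L))
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("sharpening adds no trainable parameters", {
  for (bf in c(4, 16)) {
    mu <- build_model(model_spec("unet", base_filters = bf), seed = 1)
    ms <- build_model(model_spec("sharp", base_filters = bf), seed = 1)
    expect_identical(count_params(mu), count_params(ms))
  }
})

test_that("sharp_attention at depth 4 has 3 sharpening sites and 4 gates", {
  m <- build_model(model_spec("sharp_attention", depth = 4,
                              base_filters = 4), seed = 1)
  expect_identical(m$n_sharpen_sites, 3L)
  expect_identical(m$n_attention_gates, 4L)
  expect_identical(build_model(model_spec("sharp", base_filters = 4),
                               seed = 1)$n_sharpen_sites, 3L)
  expect_identical(build_model(model_spec("unet", base_filters = 4),
                               seed = 1)$n_attention_gates, 0L)
})

test_that("indivisible input sides are rejected", {
  expect_error(model_spec("unet", depth = 4, input_side = 100),
               "divisible")
})

test_that("forward passes are deterministic with dropout off", {
  m <- build_model(model_spec("sharp_attention", base_filters = 4,
                              input_side = 32), seed = 9)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(predict_probs(m, x), predict_probs(m, x))
})

test_that("analytic gradients match finite differences on a tiny model", {
  for (v in c("unet", "sharp_attention")) {
    spec <- model_spec(v, depth = 2, base_filters = 2, input_side = 8,
                       dropout_encoder = 0, dropout_decoder = 0)
    m <- build_model(spec, seed = 3)
    set.seed(41)
    x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
    y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
    lossfn <- function(params) {
      fw <- sharpseg:::net_forward(params, spec, x, train = FALSE)
      bce_dice_loss(y, fw$p)$total
    }
    fw <- sharpseg:::net_forward(m$params, spec, x, train = FALSE)
    dz <- sharpseg:::loss_grad_logits(y, fw$p)
    gr <- sharpseg:::net_backward(m$params, spec, fw, dz)
    eps <- 1e-5
    for (k in names(m$params)) {
      w <- m$params[[k]]
      for (i in sample(length(w), min(2, length(w)))) {
        p0 <- m$params
        p0[[k]][i] <- w[i] + eps; lp <- lossfn(p0)
        p0[[k]][i] <- w[i] - eps; lm <- lossfn(p0)
        num <- (lp - lm) / (2 * eps)
        expect_equal(gr[[k]][i], num, tolerance = 2e-3)
      }
    }
  }
})

test_that("every trainable weight receives gradient on a random batch", {
  spec <- model_spec("sharp_attention", depth = 2, base_filters = 2,
                     input_side = 16, dropout_encoder = 0,
                     dropout_decoder = 0)
  m <- build_model(spec, seed = 6)
  set.seed(10)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 1, 2))
  fw <- sharpseg:::net_forward(m$params, spec, x, train = FALSE)
  gr <- sharpseg:::net_backward(m$params, spec, fw,
                                sharpseg:::loss_grad_logits(y, fw$p))
  for (k in names(m$params)) {
    expect_gt(max(abs(gr[[k]])), 0, label = paste("gradient of", k))
  }
})
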