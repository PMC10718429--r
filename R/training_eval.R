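#' Training configuration
#'
#' Defaults follow the reference protocol: 300 epochs, batch size 32, Adam
#' with learning rate 0.001, beta1 = 0.9, beta2 = 0.9 and epsilon = 1e-7.
#' Note that beta2 = 0.9 is deliberate (it is the published setting), not
#' the conventional Adam default of 0.999. The best model is checkpointed on
#' the validation soft Dice and training stops early after
#' `early_stop_patience` non-improving epochs.
#'
#' @param epochs maximum epochs (default 300).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 50).
#' @param seed integer seed controlling shuffling, augmentation draws and
#'   dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 300, batch_size = 32,
                            learning_rate = 0.001, beta1 = 0.9, beta2 = 0.9,
                            epsilon = 1e-7, early_stop_patience = 50,
                            seed = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Load records into model-ready arrays
#'
#' Reads each image/mask pair, optionally applies CLAHE at native
#' resolution, then resizes to `side x side` (bilinear image, nearest
#' mask). Images are kept on the 0-255 scale; [train_model()] and
#' [predict_probs()] expect inputs scaled to [0, 1], which the training and
#' evaluation entry points do internally.
#'
#' @param records record `data.frame` from [scan_busi_layout()].
#' @param side network input side.
#' @param clahe NULL to skip enhancement, or a [clahe_config()].
#' @return list of arrays `x` (side, side, 1, n) with intensities 0-255 and
#'   `y` (side, side, 1, n) binary.
#' @export
prepare_arrays <- function(records, side, clahe = NULL) {
  n <- nrow(records)
  x <- array(0, c(side, side, 1, n))
  y <- array(0, c(side, side, 1, n))
  for (i in seq_len(n)) {
    img <- read_image(records$image_path[i])
    if (!is.null(clahe)) img <- apply_clahe(img, clahe)
    msk <- load_record_mask(records$mask_path[i])
    rp <- resize_pair(img, msk, side)
    x[, , 1, i] <- rp$image
    y[, , 1, i] <- rp$mask
  }
  list(x = x, y = y)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  lr <- cfg$learning_rate
  corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    params[[k]] <- params[[k]] -
      corr * state$m[[k]] / (sqrt(state$v[[k]]) + cfg$epsilon)
  }
  list(params = params, state = state)
}

# soft Dice over a whole set, computed in chunks without augmentation
soft_dice_set <- function(model, x, y, batch_size = 16L) {
  p <- predict_probs(model, x, batch_size)
  dice_coefficient(y, p)
}

#' Train a segmentation model
#'
#' Minimizes the BCE-Dice loss over shuffled minibatches of the training
#' set, with each sample independently augmented per epoch when an
#' augmentation configuration is supplied. After every epoch the model is
#' evaluated (un-augmented, dropout off) on the validation set by soft Dice;
#' the best weights are checkpointed and restored at the end, and training
#' stops after `early_stop_patience` epochs without improvement.
#'
#' @param model a `sharpseg_model` from [build_model()].
#' @param data_train,data_val lists with arrays `x` (intensities 0-255) and
#'   `y` (binary), as produced by [prepare_arrays()].
#' @param tcfg a [training_config()].
#' @param acfg an [augmentation_config()], or NULL for no augmentation.
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `history` (per-epoch
#'   `data.frame` with `epoch`, `train_loss`, `val_dice`) and `best_epoch`.
#' @export
train_model <- function(model, data_train, data_val, tcfg = training_config(),
                        acfg = augmentation_config(), verbose = FALSE) {
  if (dim(data_train$x)[4] == 0) stop("empty training split")
  spec <- model$spec
  params <- model$params
  side <- dim(data_train$x)[1]
  ntr <- dim(data_train$x)[4]
  state <- adam_init(params)
  best <- list(dice = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_dice = numeric())
  set.seed(tcfg$seed)
  stall <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0; nb <- 0L
    for (at in seq(1, ntr, by = tcfg$batch_size)) {
      sel <- ord[at:min(at + tcfg$batch_size - 1, ntr)]
      nbatch <- length(sel)
      xb <- array(0, c(side, side, 1, nbatch))
      yb <- array(0, c(side, side, 1, nbatch))
      for (j in seq_along(sel)) {
        img <- data_train$x[, , 1, sel[j]]
        msk <- data_train$y[, , 1, sel[j]]
        if (!is.null(acfg)) {
          tp <- sample_transform(acfg)
          w <- apply_transform(img, msk, tp)
          img <- w$image; msk <- w$mask
        }
        xb[, , 1, j] <- img / 255
        yb[, , 1, j] <- msk
      }
      fw <- net_forward(params, spec, xb, train = TRUE)
      lt <- bce_dice_loss(yb, fw$p)
      ep_loss <- ep_loss + lt$total; nb <- nb + 1L
      dz <- loss_grad_logits(yb, fw$p)
      gr <- net_backward(params, spec, fw, dz)
      st <- adam_step(params, gr, state, tcfg)
      params <- st$params; state <- st$state
    }
    mtmp <- structure(list(spec = spec, params = params),
                      class = "sharpseg_model")
    vd <- soft_dice_set(mtmp, data_val$x / 255, data_val$y)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_dice = vd))
    if (verbose)
      message(sprintf("epoch %3d  train_loss %.4f  val_dice %.4f",
                      ep, ep_loss / nb, vd))
    if (vd > best$dice) {
      best <- list(dice = vd, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tcfg$early_stop_patience) break
    }
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val_dice = best$dice)
}

# d(BCE + DiceLoss)/dz at the logits, for p = sigmoid(z)
loss_grad_logits <- function(y, p, epsilon = 1e-5, clamp = 1e-7) {
  n <- length(y)
  dbce <- (p - y) / n
  U <- sum(y) + sum(p) + epsilon
  I <- sum(y * p)
  ddice_dp <- -(2 * y / U - 2 * I / U^2)
  dz <- dbce + ddice_dp * p * (1 - p)
  dz
}

#' Derive the binarization threshold from pooled validation pixels
#'
#' Pools all predicted probabilities and ground-truth labels, builds the
#' ROC curve and returns the Youden-optimal threshold (maximum TPR - FPR).
#' The published fallback when derivation is skipped is 0.4.
#'
#' @param probs probability array/vector.
#' @param truths binary array/vector, same length.
#' @return threshold in (0, 1).
#' @export
derive_threshold <- function(probs, truths) {
  y <- as.numeric(truths); p <- as.numeric(probs)
  if (length(unique(y)) < 2)
    stop("threshold derivation needs both classes present")
  r <- pROC::roc(response = y, predictor = p, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  th <- pROC::coords(r, "best", ret = "threshold",
                     best.method = "youden",
                     transpose = FALSE)$threshold[1]
  # pROC returns +-Inf for degenerate one-sided optima; clamp into (0, 1)
  min(max(th, 1e-6), 1 - 1e-6)
}

#' Binarize a probability map
#'
#' @param probs numeric array in [0, 1].
#' @param threshold scalar in (0, 1); pixels with `prob >= threshold`
#'   become 1.
#' @return integer array of \{0, 1\} shaped like `probs`.
#' @export
binarize <- function(probs, threshold = 0.4) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  out <- probs
  out[] <- as.integer(probs >= threshold)
  out
}

#' Evaluate a model on a test set
#'
#' Runs inference (dropout off), binarizes at the given threshold and
#' reports the pooled pixel-wise metric suite via [metrics_report()].
#'
#' @param model a `sharpseg_model`.
#' @param data list with arrays `x` (0-255) and `y` (binary), e.g. from
#'   [prepare_arrays()].
#' @param threshold binarization threshold (default 0.4).
#' @return one-row metrics `data.frame`; the probability maps are attached
#'   as attribute `"probs"`.
#' @export
evaluate_model <- function(model, data, threshold = 0.4) {
  if (dim(data$x)[4] == 0) stop("empty test set")
  probs <- predict_probs(model, data$x / 255)
  rep <- metrics_report(data$y, probs, threshold)
  attr(rep, "probs") <- probs
  rep
}
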