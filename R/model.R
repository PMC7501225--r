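## Feed-forward neural classifier for ray-cast head-shape descriptors.
##
## Architecture: input (standardized ray lengths, Gaussian noise std 0.5
## added during training only) -> for each hidden size: affine -> batch
## normalization -> leaky ReLU -> dropout -> ... -> affine -> softmax over
## the four diagnostic classes.  Trained with Adam (time-based learning-rate
## decay, global gradient-norm clipping) on categorical cross-entropy, with
## early stopping on a validation set and best-epoch weight restoration.
## Implemented directly on BLAS matrix operations; the network is small
## (751-192-128-64-32-4) and CPU training takes seconds per fold.

#' Classifier hyperparameter configuration
#'
#' Defaults are the reference configuration of the method: hidden layers of
#' 192, 128, 64 and 32 units, leaky ReLU slope 0.2, dropout rate 0.5, batch
#' normalization momentum 0.8 (fraction of the moving statistic retained per
#' batch), Gaussian input noise with standard deviation 0.5 (on standardized
#' features, training only), Adam with learning rate 1e-3, time-based decay
#' 1e-6 per step and global gradient-norm clip 0.001, batch size 256, at most
#' 1000 epochs, and early-stopping patience of 50 epochs.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param leaky_relu_alpha Negative-side slope of the leaky ReLU.
#' @param dropout_rate Dropout probability in hidden blocks.
#' @param batchnorm_momentum Moving-average retention of batch statistics.
#' @param input_noise_std Std of Gaussian noise added to inputs in training.
#' @param n_classes Number of output classes (4).
#' @param learning_rate,decay,clip_norm Adam optimizer settings.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   halting.
#' @param seed Integer seed controlling initialization, shuffling, noise and
#'   dropout.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(hidden_sizes = c(192L, 128L, 64L, 32L),
                              leaky_relu_alpha = 0.2,
                              dropout_rate = 0.5,
                              batchnorm_momentum = 0.8,
                              input_noise_std = 0.5,
                              n_classes = 4L,
                              learning_rate = 1e-3,
                              decay = 1e-6,
                              clip_norm = 0.001,
                              batch_size = 256L,
                              max_epochs = 1000L,
                              early_stop_patience = 50L,
                              seed = 1L) {
  stopifnot(length(hidden_sizes) >= 1L, all(hidden_sizes >= 1L),
            leaky_relu_alpha >= 0, dropout_rate >= 0, dropout_rate < 1,
            batchnorm_momentum >= 0, batchnorm_momentum <= 1,
            input_noise_std >= 0, n_classes >= 2L,
            learning_rate >= 0, decay >= 0, clip_norm > 0,
            batch_size >= 1L, max_epochs >= 1L, early_stop_patience >= 1L)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 leaky_relu_alpha = leaky_relu_alpha,
                 dropout_rate = dropout_rate,
                 batchnorm_momentum = batchnorm_momentum,
                 input_noise_std = input_noise_std,
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate, decay = decay,
                 clip_norm = clip_norm, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

## ---- parameter container ----

# weights: list per layer; hidden layer l has W, b, gamma, beta (+ running
# mean/var, non-trainable); the output layer has W, b only.
mlp_init <- function(n_input, config) {
  sizes <- c(n_input, config$hidden_sizes)
  layers <- vector("list", length(config$hidden_sizes) + 1L)
  for (l in seq_along(config$hidden_sizes)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))        # Glorot uniform
    layers[[l]] <- list(
      W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = numeric(fan_out),
      gamma = rep(1, fan_out), beta = numeric(fan_out),
      run_mean = numeric(fan_out), run_var = rep(1, fan_out))
  }
  fan_in <- sizes[length(sizes)]; fan_out <- config$n_classes
  lim <- sqrt(6 / (fan_in + fan_out))
  layers[[length(layers)]] <- list(
    W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
    b = numeric(fan_out))
  layers
}

mlp_n_params <- function(layers) {
  sum(vapply(layers, function(L) {
    length(L$W) + length(L$b) +
      if (!is.null(L$gamma)) length(L$gamma) + length(L$beta) else 0L
  }, numeric(1)))
}

BN_EPS <- 1e-3   # batch-norm variance epsilon

# row-vector broadcasting without sweep()'s aperm overhead
add_rv <- function(m, v) m + rep(v, each = nrow(m))
mul_rv <- function(m, v) m * rep(v, each = nrow(m))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; training = TRUE uses batch statistics, dropout and input
# noise (consuming RNG), and returns the caches needed for backprop
mlp_forward <- function(layers, x, config, training = FALSE) {
  nh <- length(config$hidden_sizes)
  caches <- if (training) vector("list", nh) else NULL
  h <- x
  if (training && config$input_noise_std > 0)
    h <- h + matrix(rnorm(length(h), sd = config$input_noise_std), nrow(h), ncol(h))
  alpha <- config$leaky_relu_alpha
  for (l in seq_len(nh)) {
    L <- layers[[l]]
    z <- add_rv(h %*% L$W, L$b)
    if (training) {
      mu <- colMeans(z)
      zc <- add_rv(z, -mu)
      var <- colMeans(zc^2)
      inv_sd <- 1 / sqrt(var + BN_EPS)
      zhat <- mul_rv(zc, inv_sd)
    } else {
      zhat <- mul_rv(add_rv(z, -L$run_mean), 1 / sqrt(L$run_var + BN_EPS))
    }
    a_pre <- add_rv(mul_rv(zhat, L$gamma), L$beta)
    act <- a_pre * (alpha + (1 - alpha) * (a_pre > 0))
    if (training && config$dropout_rate > 0) {
      keep <- 1 - config$dropout_rate
      mask <- matrix(runif(length(act)) < keep, nrow(act), ncol(act)) / keep
      out <- act * mask
    } else {
      mask <- NULL
      out <- act
    }
    if (training)
      caches[[l]] <- list(h_in = h, zhat = zhat, inv_sd = inv_sd,
                          a_pre = a_pre, mask = mask, mu = mu, var = var)
    h <- out
  }
  Lout <- layers[[nh + 1L]]
  logits <- add_rv(h %*% Lout$W, Lout$b)
  list(probs = softmax_rows(logits), h_last = h, caches = caches)
}

# gradients of mean categorical cross-entropy wrt all trainable parameters
mlp_backward <- function(layers, fwd, y_onehot, config) {
  nh <- length(config$hidden_sizes)
  n <- nrow(y_onehot)
  grads <- vector("list", nh + 1L)
  delta <- (fwd$probs - y_onehot) / n            # d loss / d logits
  Lout <- layers[[nh + 1L]]
  grads[[nh + 1L]] <- list(W = crossprod(fwd$h_last, delta), b = colSums(delta))
  dh <- tcrossprod(delta, Lout$W)                # delta %*% t(W)
  for (l in rev(seq_len(nh))) {
    L <- layers[[l]]
    cc <- fwd$caches[[l]]
    if (!is.null(cc$mask)) dh <- dh * cc$mask
    alpha <- config$leaky_relu_alpha
    dact <- dh * (alpha + (1 - alpha) * (cc$a_pre > 0))
    dgamma <- colSums(dact * cc$zhat)
    dbeta <- colSums(dact)
    dzhat <- mul_rv(dact, L$gamma)
    # batch-norm backward (batch statistics)
    m <- nrow(dzhat)
    t1 <- colSums(dzhat)
    t2 <- colSums(dzhat * cc$zhat)
    dz <- mul_rv(add_rv(dzhat, -t1 / m) - mul_rv(cc$zhat, t2 / m), cc$inv_sd)
    grads[[l]] <- list(W = crossprod(cc$h_in, dz), b = colSums(dz),
                       gamma = dgamma, beta = dbeta)
    if (l > 1L) dh <- tcrossprod(dz, L$W) else dh <- NULL
  }
  grads
}

# flatten/unflatten trainable parameters for the optimizer
trainable_names <- function(L) intersect(c("W", "b", "gamma", "beta"), names(L))

adam_state_init <- function(layers) {
  lapply(layers, function(L) {
    s <- list()
    for (nm in trainable_names(L))
      s[[nm]] <- list(m = L[[nm]] * 0, v = L[[nm]] * 0)
    s
  })
}

adam_step <- function(layers, grads, state, step, config) {
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  lr <- config$learning_rate / (1 + config$decay * step)
  # global gradient-norm clipping across every trainable tensor
  gsq <- 0
  for (l in seq_along(grads)) for (nm in trainable_names(grads[[l]]))
    gsq <- gsq + sum(grads[[l]][[nm]]^2)
  gnorm <- sqrt(gsq)
  scale <- if (gnorm > config$clip_norm) config$clip_norm / gnorm else 1
  bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
  for (l in seq_along(grads)) {
    for (nm in trainable_names(grads[[l]])) {
      g <- grads[[l]][[nm]] * scale
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[l]][[nm]] <- st
      layers[[l]][[nm]] <- layers[[l]][[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}

cross_entropy <- function(probs, y_onehot) {
  -mean(log(pmax(rowSums(probs * y_onehot), 1e-12)))
}

one_hot <- function(y, classes = CRANIO_CLASSES) {
  y <- factor(as.character(y), levels = classes)
  if (anyNA(y)) stop("labels outside the class set")
  m <- matrix(0, length(y), length(classes))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  colnames(m) <- classes
  m
}

#' Fit the feed-forward head-shape classifier
#'
#' Trains the network on standardized descriptor rows with early stopping on
#' a validation set: after each epoch the validation categorical
#' cross-entropy is computed in inference mode (no noise, no dropout, moving
#' batch-norm statistics); if it fails to improve for
#' `config$early_stop_patience` consecutive epochs training halts and the
#' weights of the best validation epoch are restored.  Training is
#' deterministic given `config$seed`.
#'
#' @param x Numeric matrix of standardized features (rows = samples).
#' @param y Class labels (character or factor over [cranio_classes()]).
#' @param val_x,val_y Validation features and labels (required: early
#'   stopping is undefined without them).
#' @param config A [classifier_config()].
#' @param classes Class-label order; defaults to [cranio_classes()].
#' @param verbose Print per-epoch losses every 25 epochs.
#' @return An object of class `cranionet`: list with `layers` (weights),
#'   `config`, `classes`, `history` (data.frame epoch/train_loss/val_loss),
#'   `best_epoch`, `stopped_epoch`, `n_params`.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- matrix(rnorm(200 * 10), 200)
#' y <- rep(c("healthy", "scaphocephaly"), each = 100)
#' x[y == "scaphocephaly", 1] <- x[y == "scaphocephaly", 1] + 4
#' cfg <- classifier_config(hidden_sizes = c(16, 8), max_epochs = 60,
#'                          batch_size = 64, seed = 1)
#' fit <- cranionet(x[1:160, ], y[1:160], x[161:200, ], y[161:200], cfg)
#' predict(fit, x[196:200, ])
#' }
#' @export
cranionet <- function(x, y, val_x, val_y, config = classifier_config(),
                      classes = cranio_classes(), verbose = FALSE) {
  x <- as.matrix(x)
  if (missing(val_x) || is.null(val_x) || NROW(val_x) == 0L)
    stop("empty validation set: early stopping is undefined without one")
  val_x <- as.matrix(val_x)
  if (ncol(val_x) != ncol(x)) stop("validation feature size mismatch")
  y1 <- one_hot(y, classes)
  vy1 <- one_hot(val_y, classes)
  cfg <- config
  cfg$n_classes <- length(classes)

  fit <- with_seed(cfg$seed, {
    layers <- mlp_init(ncol(x), cfg)
    cpp_train_mlp(x, y1, val_x, vy1, layers, cfg)
  })
  history <- data.frame(epoch = seq_along(fit$val_loss),
                        train_loss = fit$train_loss, val_loss = fit$val_loss)
  if (verbose)
    message(sprintf("trained %d epochs; best validation epoch %d (loss %.4f)",
                    fit$stopped_epoch, fit$best_epoch,
                    min(fit$val_loss)))

  structure(list(layers = fit$layers, config = cfg, classes = classes,
                 history = history, best_epoch = fit$best_epoch,
                 stopped_epoch = fit$stopped_epoch,
                 n_params = mlp_n_params(fit$layers)),
            class = "cranionet")
}

#' @export
print.cranionet <- function(x, ...) {
  cat("cranionet feed-forward classifier\n")
  cat("  architecture:", nrow(x$layers[[1]]$W), "->",
      paste(x$config$hidden_sizes, collapse = " -> "), "->",
      length(x$classes), "(softmax)\n")
  cat("  trainable parameters:", x$n_params, "\n")
  cat(sprintf("  trained %d epochs (best validation epoch %d, val loss %.4f)\n",
              x$stopped_epoch, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.cranionet <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4f; min val loss %.4f at epoch %d of %d\n",
              h$train_loss[nrow(h)], min(h$val_loss), object$best_epoch, nrow(h)))
  invisible(object)
}

#' Predict classes or probabilities
#'
#' Inference is deterministic: input noise and dropout are inactive and
#' batch normalization uses its moving statistics.  Ties in the
#' argmax are broken toward the lowest class index in the fixed order.
#'
#' @param object A fitted `cranionet`.
#' @param newdata Numeric matrix (or vector) of standardized features.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a probability matrix with one row
#'   per sample (rows sum to 1).
#' @export
predict.cranionet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- if (is.matrix(newdata)) newdata else matrix(as.numeric(newdata), nrow = 1)
  if (ncol(m) != nrow(object$layers[[1]]$W))
    stop("feature size ", ncol(m), " does not match network input size ",
         nrow(object$layers[[1]]$W))
  probs <- mlp_forward(object$layers, m, object$config, training = FALSE)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  idx <- apply(probs, 1, which.max)    # which.max takes the first maximum
  factor(object$classes[idx], levels = object$classes)
}

#' Plot the training history
#'
#' @param x A fitted `cranionet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cranionet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "categorical cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted classifier as JSON
#'
#' The container maps layer names (`hidden1` ... `output`) to their tensors
#' (`W`, `b`, and for hidden layers `gamma`, `beta`, `run_mean`, `run_var`)
#' and stores the configuration, class order and training history alongside,
#' so a saved model is fully self-describing.
#'
#' @param object A fitted `cranionet`.
#' @param path JSON file path.
#' @return `write_cranionet`: invisibly `path`; `read_cranionet`: a
#'   `cranionet` whose predictions match the saved model.
#' @export
write_cranionet <- function(object, path) {
  stopifnot(inherits(object, "cranionet"))
  nh <- length(object$config$hidden_sizes)
  layers <- object$layers
  names(layers) <- c(paste0("hidden", seq_len(nh)), "output")
  layers <- lapply(layers, function(L) {
    L$W <- unclass(L$W)
    lapply(L, unname)
  })
  jsonlite::write_json(
    list(format = "craniorays-mlp-1",
         config = unclass(object$config), classes = object$classes,
         layers = layers, history = object$history,
         best_epoch = object$best_epoch, stopped_epoch = object$stopped_epoch),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cranionet
#' @export
read_cranionet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "craniorays-mlp-1"))
    stop("not a craniorays model file: ", path)
  cfg <- do.call(classifier_config, obj$config)
  layers <- lapply(unname(obj$layers), function(L) {
    L$W <- as.matrix(L$W)
    L
  })
  structure(list(layers = layers, config = cfg, classes = obj$classes,
                 history = as.data.frame(obj$history),
                 best_epoch = obj$best_epoch, stopped_epoch = obj$stopped_epoch,
                 n_params = mlp_n_params(layers)),
            class = "cranionet")
}
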