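test_that("activation variants follow their closed forms", {
  expect_equal(activation(-3, "standard_relu"), 0)
  expect_equal(activation(2.5, "standard_relu"), 2.5)
  expect_equal(activation(0, "eq6_softplus"), log(2))
  # numerically stable at large magnitudes
  expect_equal(activation(50, "eq6_softplus"), 50, tolerance = 1e-12)
  expect_equal(activation(-50, "eq6_softplus"), 0, tolerance = 1e-12)
  expect_false(any(!is.finite(activation(c(-1e4, 1e4), "eq6_softplus"))))
})

test_that("losses match brute-force sums", {
  expect_equal(binary_ce(1, 0.5), log(2))
  expect_equal(binary_ce(c(1, 0), c(1, 0)), binary_ce(c(1, 0), c(1, 0)))
  expect_lt(binary_ce(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  set.seed(2)
  for (s in 1:5) {
    y <- sample(0:1, 4, replace = TRUE)
    p <- runif(4, 0.05, 0.95)
    manual <- -mean(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(binary_ce(y, p), manual, tolerance = 1e-12)
  }

  Y <- diag(3)[, c(1, 2, 3, 1)]
  P <- matrix(1 / 3, 3, 4)
  expect_equal(categorical_ce(Y, P), log(3), tolerance = 1e-9)
  expect_lt(categorical_ce(Y, pmin(pmax(Y, 1e-7), 1 - 1e-7)), 1e-5)
  set.seed(3)
  P2 <- matrix(rexp(12), 3)
  P2 <- sweep(P2, 2, colSums(P2), "/")
  manual <- -mean(colSums(Y * log(P2)))
  expect_equal(categorical_ce(Y, P2), manual, tolerance = 1e-12)
})

test_that("the default architecture matches the selected configuration", {
  cfg <- model_config()
  expect_equal(cfg$filters, c(64L, 32L, 32L, 16L))
  expect_equal(cfg$kernels, c(5L, 5L, 3L, 1L))
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$learning_rate, 0.005)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$dropout_conv, 0.25)
  expect_equal(cfg$dropout_fc, 0.5)
  expect_equal(cfg$epochs, 100L)

  m2 <- build_model(cfg, n_in = 64, n_classes = 2, seed = 1)
  convs <- Filter(function(l) l$type == "conv", m2$layers)
  expect_equal(length(convs), 4)
  expect_equal(vapply(convs, function(l) nrow(l$W), 0L),
               c(64L, 32L, 32L, 16L))
  expect_equal(sum(vapply(convs, function(l) l$has_bn, TRUE)), 3)
  expect_equal(sum(vapply(convs, function(l) l$dropout > 0, TRUE)), 2)
  expect_equal(sum(vapply(convs, function(l) l$pool, TRUE)), 1)
  expect_equal(m2$head, "sigmoid_binary")
  expect_equal(emoselect:::resolve_optimizer(m2), "adadelta")

  m3 <- build_model(cfg, n_in = 64, n_classes = 3, seed = 1)
  expect_equal(m3$head, "softmax_3class")
  expect_equal(emoselect:::resolve_optimizer(m3), "adam")
  expect_equal(nrow(m3$layers[[length(m3$layers)]]$W), 3)

  # parameter count is a pure function of the configuration
  expect_equal(n_parameters(build_model(cfg, 64, 2, seed = 1)),
               n_parameters(build_model(cfg, 64, 2, seed = 99)))
  expect_error(build_model(cfg, n_in = 3, n_classes = 2),
               class = "emoselect_cnn_error")
  expect_error(build_model(cfg, n_in = 63, n_classes = 2),
               class = "emoselect_cnn_error")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(conv_layers = 3, filters = c(4, 3, 2),
                      kernels = c(3, 3, 1), dropout_conv = 0,
                      dropout_fc = 0, fc_units = 5,
                      activation = "eq6_softplus")
  mdl <- build_model(cfg, n_in = 32, n_classes = 2, seed = 3)
  set.seed(11)
  X <- matrix(rnorm(32 * 4), 32, 4)
  y <- c(0, 1, 0, 1)
  loss_fn <- function(m) {
    binary_ce(y, model_forward(m, X, training = TRUE)$out)
  }
  fw <- model_forward(mdl, X, training = TRUE)
  grads <- model_backward(mdl, fw, (fw$out - matrix(y, 1)) / 4)
  worst <- 0
  for (li in seq_along(mdl$layers)) {
    for (slot in c("W", "b", "gamma", "beta")) {
      p <- mdl$layers[[li]][[slot]]
      g <- emoselect:::grad_of(grads, li, slot)
      if (is.null(p) || is.null(g)) next
      set.seed(li)
      for (j in sample(length(p), min(6, length(p)))) {
        eps <- 1e-5
        up <- mdl; up$layers[[li]][[slot]][j] <- p[j] + eps
        dn <- mdl; dn$layers[[li]][[slot]][j] <- p[j] - eps
        num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
        worst <- max(worst, abs(num - g[j]) /
                       max(abs(num) + abs(g[j]), 1e-7))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training learns separable data and respects null updates", {
  set.seed(6)
  n <- 48
  n_in <- 64
  X <- matrix(rnorm(n_in * n), n_in, n)
  y <- factor(rep(c("low", "high"), each = n / 2),
              levels = c("low", "high"))
  X[, y == "high"] <- X[, y == "high"] + 2 * sin(2 * pi * (1:n_in) / 16)
  cfg <- model_config(conv_layers = 2, filters = c(8, 4),
                      kernels = c(5, 3), fc_units = 8, batch_size = 16)
  mdl <- build_model(cfg, n_in, 2, seed = 2)
  fit <- train(mdl, X, y, epochs = 10, seed = 2)
  h <- tidy(fit)
  expect_equal(nrow(h), 10)
  expect_lt(h$loss[10], h$loss[1])
  expect_gt(h$accuracy[10], 0.9)
  expect_s3_class(predict(fit, X), "factor")
  pr <- predict(fit, X, type = "prob")
  expect_equal(dim(pr), c(2, n))
  expect_equal(colSums(pr), rep(1, n), tolerance = 1e-9)

  # identical seed, identical fit
  fit2 <- train(build_model(cfg, n_in, 2, seed = 2), X, y,
                epochs = 3, seed = 5)
  fit3 <- train(build_model(cfg, n_in, 2, seed = 2), X, y,
                epochs = 3, seed = 5)
  expect_identical(fit2$history, fit3$history)

  # zero learning rate leaves the weights untouched (SGD path)
  # full-batch so batch statistics are identical across epochs
  cfg0 <- model_config(conv_layers = 2, filters = c(8, 4),
                       kernels = c(5, 3), fc_units = 8,
                       batch_size = 48, learning_rate = 0,
                       dropout_conv = 0, dropout_fc = 0,
                       optimizer = "sgd")
  m0 <- build_model(cfg0, n_in, 2, seed = 4)
  f0 <- train(m0, X, y, epochs = 2, seed = 4)
  expect_equal(f0$layers[[1]]$W, m0$layers[[1]]$W)
  expect_equal(f0$layers[[4]]$W, m0$layers[[4]]$W)
  expect_equal(diff(f0$history$loss), 0, tolerance = 1e-6)

  # label arity must match the head
  expect_error(train(build_model(cfg, n_in, 3, seed = 1), X, y),
               class = "emoselect_cnn_error")
})

test_that("3-class head trains with the adam pairing", {
  set.seed(8)
  n <- 36
  n_in <- 32
  X <- matrix(rnorm(n_in * n), n_in, n)
  y <- factor(rep(c("neg", "neu", "pos"), each = n / 3))
  shift <- cbind(sin(2 * pi * (1:n_in) / 8), 0,
                 -sin(2 * pi * (1:n_in) / 8))
  for (k in 1:3) X[, as.integer(y) == k] <-
    X[, as.integer(y) == k] + 2 * shift[, k]
  cfg <- model_config(conv_layers = 2, filters = c(8, 4),
                      kernels = c(5, 3), fc_units = 8, batch_size = 12)
  fit <- train(build_model(cfg, n_in, 3, seed = 2), X, y,
               epochs = 30, seed = 2)
  expect_gt(tail(tidy(fit)$accuracy, 1), 0.8)
})

test_that("grid search returns the argmax and prefers fewer parameters", {
  set.seed(10)
  n_in <- 32
  X <- matrix(rnorm(n_in * 40), n_in, 40)
  y <- factor(rep(c("a", "b"), 20))
  X[, y == "b"] <- X[, y == "b"] + 1.5
  base <- model_config(conv_layers = 2, filters = c(4, 2),
                       kernels = c(3, 1), fc_units = 4, batch_size = 20)
  # grid of one point returns that point
  one <- grid_search(X, y, X, y,
                     space = list(learning_rate = 0.005),
                     base = base, epochs = 2, seed = 1)
  expect_equal(one$best_config$learning_rate, 0.005)
  expect_equal(nrow(one$results), 1)

  # the reference selected values are representable as a grid point
  space <- list(
    conv_layers = 4, filters = list(c(64, 32, 32, 16)),
    kernels = list(c(5, 5, 3, 1)), batch_size = c(32, 64),
    learning_rate = c(0.005), momentum = 0.9
  )
  grid_n <- prod(lengths(space))
  expect_equal(grid_n, 2)
  cfgs <- do.call(model_config, c(list(), lapply(space, function(v) {
    if (is.list(v)) v[[1]] else v[1]
  })))
  expect_equal(cfgs$filters, c(64L, 32L, 32L, 16L))

  res <- grid_search(X, y, X, y,
                     space = list(fc_units = c(4, 8)),
                     base = base, epochs = 2, seed = 1)
  expect_equal(nrow(res$results), 2)
  best_row <- res$results[which.max(res$results$val_accuracy), ]
  expect_equal(res$best_config$fc_units, best_row$fc_units)
  res2 <- grid_search(X, y, X, y,
                      space = list(fc_units = c(4, 8)),
                      base = base, epochs = 2, seed = 1)
  expect_identical(res$results, res2$results)
})
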