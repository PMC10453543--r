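#' Hyperparameter configuration of the 1D-CNN
#'
#' Defaults are the selected values of the model's grid search: four
#' convolutional layers with (64, 32, 32, 16) filters and kernel sizes
#' (5, 5, 3, 1), batch size 64, learning rate 0.005, momentum 0.9,
#' dropout 0.25 inside the first two convolution blocks and 0.5 before
#' the output layer, 100 epochs. The binary head is a single sigmoid
#' unit trained with Adadelta and binary cross-entropy; the 3-class
#' head is a softmax trained with Adam and categorical cross-entropy.
#' For Adadelta the `momentum` value is applied as the decay rate rho
#' of the squared-gradient and squared-update accumulators (Adadelta's
#' own learning rate is the adaptive RMS ratio; `learning_rate` applies
#' to the Adam/SGD paths).
#'
#' @param conv_layers Number of convolutional layers.
#' @param filters Integer vector of filters per layer.
#' @param kernels Integer vector of kernel sizes per layer.
#' @param batch_size Mini-batch size.
#' @param learning_rate Learning rate (Adam/SGD).
#' @param momentum Momentum / Adadelta decay rho.
#' @param dropout_conv Dropout probability inside conv blocks.
#' @param dropout_fc Dropout probability before the output layer.
#' @param epochs Training epochs.
#' @param activation Activation variant, see [activation()].
#' @param optimizer `"auto"` (Adadelta for binary, Adam for 3-class),
#'   `"adadelta"`, `"adam"` or `"sgd"`.
#' @param fc_units Width of the hidden fully connected layer.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_layers = 4,
                         filters = c(64, 32, 32, 16),
                         kernels = c(5, 5, 3, 1),
                         batch_size = 64,
                         learning_rate = 0.005,
                         momentum = 0.9,
                         dropout_conv = 0.25,
                         dropout_fc = 0.5,
                         epochs = 100,
                         activation = c("standard_relu", "eq6_softplus"),
                         optimizer = c("auto", "adadelta", "adam", "sgd"),
                         fc_units = 64) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  stopifnot(length(filters) == conv_layers,
            length(kernels) == conv_layers,
            all(filters >= 1), all(kernels >= 1),
            batch_size >= 1, learning_rate >= 0,
            momentum >= 0, momentum < 1,
            dropout_conv >= 0, dropout_conv < 1,
            dropout_fc >= 0, dropout_fc < 1, epochs >= 1)
  structure(
    list(conv_layers = conv_layers, filters = as.integer(filters),
         kernels = as.integer(kernels),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, momentum = momentum,
         dropout_conv = dropout_conv, dropout_fc = dropout_fc,
         epochs = as.integer(epochs), activation = activation,
         optimizer = optimizer, fc_units = as.integer(fc_units)),
    class = "model_config"
  )
}

#' Build an (untrained) 1D-CNN
#'
#' Layer sequence for the default 4-layer configuration:
#' conv+BN+act+dropout(0.25), conv+BN+act+dropout(0.25),
#' conv+BN+act+avgpool(2), conv+act, flatten, FC+act, dropout(0.5),
#' FC-output. With more/fewer conv layers the pooling stays attached to
#' the penultimate block and BN to all but the last block. The head is
#' a single sigmoid unit for 2 classes and a softmax for 3+.
#' Weights are seeded uniform fan-in initialized, so two builds with
#' the same config and seed are identical.
#'
#' @param config A [model_config()].
#' @param n_in Input vector length (channels x window samples x
#'   windows for the pipeline's concatenated input).
#' @param n_classes 2 for the sigmoid/binary head, 3+ for softmax.
#' @param seed Integer seed for weight initialization.
#' @return A `cnn_model` (untrained; `$history` is empty).
#' @export
build_model <- function(config = model_config(), n_in, n_classes,
                        seed = 1L) {
  stopifnot(inherits(config, "model_config"), is_count(n_in),
            n_classes >= 2)
  nc <- config$conv_layers
  if (n_in < max(config$kernels)) {
    abort("n_in is smaller than the largest kernel.",
          class = "emoselect_cnn_error")
  }
  if (n_in %% 2 != 0) {
    abort("n_in must be even (one average-pooling layer of size 2).",
          class = "emoselect_cnn_error")
  }
  layers <- list()
  C <- 1L
  L <- as.integer(n_in)
  local_seed(seed, {
    for (i in seq_len(nc)) {
      k <- config$kernels[i]
      f <- config$filters[i]
      layers[[length(layers) + 1]] <- list(
        type = "conv", W = init_mat(f, k * C), b = rep(0, f),
        k = k, C_in = C, has_bn = i < nc,
        gamma = rep(1, f), beta = rep(0, f),
        running = list(mean = rep(0, f), var = rep(1, f)),
        dropout = if (i <= 2 && i < nc) config$dropout_conv else 0,
        pool = i == max(1, nc - 1)
      )
      C <- f
      if (i == max(1, nc - 1)) L <- L %/% 2L
    }
    n_flat <- C * L
    layers[[length(layers) + 1]] <- list(
      type = "dense", W = init_mat(config$fc_units, n_flat),
      b = rep(0, config$fc_units), act = TRUE,
      dropout = config$dropout_fc
    )
    n_out <- if (n_classes == 2) 1L else as.integer(n_classes)
    layers[[length(layers) + 1]] <- list(
      type = "dense", W = init_mat(n_out, config$fc_units),
      b = rep(0, n_out), act = FALSE, dropout = 0
    )
  })
  structure(
    list(config = config, layers = layers, n_in = as.integer(n_in),
         n_classes = as.integer(n_classes),
         head = if (n_classes == 2) "sigmoid_binary" else
           "softmax_3class",
         seed = as.integer(seed), history = NULL, class_levels = NULL),
    class = "cnn_model"
  )
}

init_mat <- function(n_out, n_in) {
  # uniform fan-in initialization
  lim <- sqrt(1 / n_in)
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' @exportS3Method base::print
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> input", x$n_in, "->",
    paste0(x$config$filters, "@", x$config$kernels, collapse = " -> "),
    "-> fc", x$config$fc_units, "->", x$head, "\n")
  cat("  parameters:", n_parameters(x),
      if (is.null(x$history)) "(untrained)" else
        paste0("(trained ", nrow(x$history), " epochs)"), "\n")
  invisible(x)
}

#' Number of trainable parameters of a CNN
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    n <- length(l$W) + length(l$b)
    if (identical(l$type, "conv") && l$has_bn) {
      n <- n + length(l$gamma) + length(l$beta)
    }
    n
  }, 0))
}

# Forward pass. X: n_in x B matrix. Returns output plus caches for
# backprop. Dropout masks are drawn from the current RNG stream when
# training.
model_forward <- function(model, X, training = FALSE) {
  B <- ncol(X)
  caches <- vector("list", length(model$layers))
  M <- matrix(X, nrow = 1) # C=1, columns (b-1)*L + t
  L <- model$n_in
  act_var <- model$config$activation
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    cache <- list(L = L)
    if (l$type == "conv") {
      cv <- conv1d_forward(M, l$W, l$b, l$k, L, B)
      cache$conv <- cv
      Z <- cv$Z
      if (l$has_bn) {
        bn <- bn_forward(Z, l$gamma, l$beta, l$running, training,
                         momentum = model$config$momentum)
        cache$bn <- bn
        cache$bn_in <- Z
        Z <- bn$Z
        if (training) model$layers[[li]]$running <- bn$running
      }
      cache$pre_act <- Z
      Z <- activation(Z, act_var)
      if (training && l$dropout > 0) {
        mask <- dropout_mask(nrow(Z), ncol(Z), l$dropout)
        cache$mask <- mask
        Z <- Z * mask
      }
      if (l$pool) {
        cache$pre_pool_L <- L
        Z <- avgpool2_forward(Z, L, B)
        L <- L %/% 2L
      }
      M <- Z
    } else {
      if (li == length(model$layers) - 1) {
        # entering dense stage: flatten C x (L*B) -> (C*L) x B
        cache$flat <- c(nrow(M), L, B)
        M <- flatten_forward(M, nrow(M), L, B)
      }
      cache$X_in <- M
      Z <- l$W %*% M + l$b
      if (l$act) {
        cache$pre_act <- Z
        Z <- activation(Z, act_var)
        if (training && l$dropout > 0) {
          mask <- dropout_mask(nrow(Z), ncol(Z), l$dropout)
          cache$mask <- mask
          Z <- Z * mask
        }
      }
      M <- Z
    }
    caches[[li]] <- cache
  }
  out <- if (model$head == "sigmoid_binary") {
    1 / (1 + exp(-M))
  } else {
    e <- exp(M - rep(apply(M, 2, max), each = nrow(M)))
    e / rep(colSums(e), each = nrow(e))
  }
  list(out = out, logits = M, caches = caches, model = model)
}

# Backward pass from d(loss)/d(logits). Returns gradient list aligned
# with model$layers.
model_backward <- function(model, fw, dlogits) {
  B <- ncol(dlogits)
  grads <- vector("list", length(model$layers))
  act_var <- model$config$activation
  dM <- dlogits
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (l$type == "dense") {
      if (l$act) {
        if (!is.null(cache$mask)) dM <- dM * cache$mask
        dM <- dM * activation_grad(cache$pre_act, act_var)
      }
      grads[[li]] <- list(dW = dM %*% t(cache$X_in), db = rowSums(dM))
      dM <- crossprod(l$W, dM)
      if (!is.null(cache$flat)) {
        dM <- unflatten_backward(dM, cache$flat[1], cache$flat[2],
                                 cache$flat[3])
      }
    } else {
      L <- cache$L
      if (l$pool) {
        dM <- avgpool2_backward(dM, cache$pre_pool_L, B)
      }
      if (!is.null(cache$mask)) dM <- dM * cache$mask
      dM <- dM * activation_grad(cache$pre_act, act_var)
      g <- list()
      if (l$has_bn) {
        bb <- bn_backward(dM, cache$bn, l$gamma)
        g$dgamma <- bb$dgamma
        g$dbeta <- bb$dbeta
        dM <- bb$dM
      }
      cb <- conv1d_backward(dM, cache$conv, l$W, l$k, L, B)
      g$dW <- cb$dW
      g$db <- cb$db
      grads[[li]] <- g
      dM <- cb$dM
    }
  }
  grads
}

#' Binary cross-entropy loss
#'
#' Mean over the batch of `-(y log yhat + (1-y) log(1-yhat))`, with
#' predictions clipped to `[eps, 1-eps]`.
#'
#' @param y 0/1 labels.
#' @param yhat Predicted probabilities in (0, 1).
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss (nats).
#' @examples
#' binary_ce(1, 0.5) # log(2)
#' @export
binary_ce <- function(y, yhat, eps = 1e-7) {
  yhat <- pmin(pmax(as.numeric(yhat), eps), 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Categorical cross-entropy loss
#'
#' Mean over the batch of `-sum_k y_k log(yhat_k)` for one-hot labels
#' and simplex predictions (columns = batch elements).
#'
#' @param y One-hot label matrix, classes x batch.
#' @param yhat Predicted probability matrix, classes x batch.
#' @param eps Clipping constant.
#' @return Scalar loss (nats).
#' @export
categorical_ce <- function(y, yhat, eps = 1e-7) {
  y <- as.matrix(y)
  yhat <- pmin(pmax(as.matrix(yhat), eps), 1 - eps)
  -mean(colSums(y * log(yhat)))
}
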