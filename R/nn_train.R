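# Optimizers. Parameters are addressed as (layer index, slot name);
# each optimizer keeps one accumulator set per parameter slot.

param_slots <- function(model) {
  out <- list()
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    slots <- c("W", "b")
    if (identical(l$type, "conv") && l$has_bn) {
      slots <- c(slots, "gamma", "beta")
    }
    for (s in slots) out[[length(out) + 1]] <- list(li = li, slot = s)
  }
  out
}

grad_of <- function(grads, li, slot) {
  switch(slot, W = grads[[li]]$dW, b = grads[[li]]$db,
         gamma = grads[[li]]$dgamma, beta = grads[[li]]$dbeta)
}

make_optimizer <- function(kind, config, model) {
  slots <- param_slots(model)
  state <- lapply(slots, function(sl) {
    p <- model$layers[[sl$li]][[sl$slot]]
    list(a = p * 0, b = p * 0, t = 0)
  })
  rho <- config$momentum
  lr <- config$learning_rate
  eps <- 1e-6
  step <- function(model, grads) {
    for (i in seq_along(slots)) {
      li <- slots[[i]]$li
      sn <- slots[[i]]$slot
      g <- grad_of(grads, li, sn)
      if (is.null(g)) next
      st <- state[[i]]
      if (kind == "adadelta") {
        # Zeiler's learning-rate-free form: the step size is the running
        # RMS ratio of past updates to past gradients
        st$a <- rho * st$a + (1 - rho) * g^2
        dx <- -sqrt(st$b + eps) / sqrt(st$a + eps) * g
        st$b <- rho * st$b + (1 - rho) * dx^2
        model$layers[[li]][[sn]] <- model$layers[[li]][[sn]] + dx
      } else if (kind == "adam") {
        st$t <- st$t + 1
        st$a <- 0.9 * st$a + 0.1 * g
        st$b <- 0.999 * st$b + 0.001 * g^2
        mhat <- st$a / (1 - 0.9^st$t)
        vhat <- st$b / (1 - 0.999^st$t)
        model$layers[[li]][[sn]] <- model$layers[[li]][[sn]] -
          lr * mhat / (sqrt(vhat) + 1e-8)
      } else { # sgd with momentum
        st$a <- rho * st$a + g
        model$layers[[li]][[sn]] <- model$layers[[li]][[sn]] -
          lr * st$a
      }
      state[[i]] <<- st
    }
    model
  }
  step
}

resolve_optimizer <- function(model) {
  if (model$config$optimizer != "auto") return(model$config$optimizer)
  if (model$head == "sigmoid_binary") "adadelta" else "adam"
}

#' Train a 1D-CNN by mini-batch backpropagation
#'
#' Binary heads train with Adadelta on binary cross-entropy, softmax
#' heads with Adam on categorical cross-entropy (overridable via the
#' config). Shuffling, dropout and all other randomness derive from
#' `seed`, so a run is reproducible bit-for-bit (single-threaded BLAS;
#' with a threaded BLAS reductions may reorder and results can differ
#' in the last float digits).
#'
#' @param model An untrained [build_model()] output.
#' @param x Input matrix, `n_in` x n_samples.
#' @param y Factor of labels (2 or `n_classes` levels).
#' @param epochs Optional override of `config$epochs`.
#' @param validation Optional `list(x =, y =)` monitored per epoch.
#' @param seed Integer seed.
#' @return The fitted `cnn_model` with a `$history` tibble (epoch,
#'   loss, accuracy, and validation columns when monitored).
#' @export
train <- function(model, x, y, epochs = NULL, validation = NULL,
                  seed = 1L) {
  stopifnot(inherits(model, "cnn_model"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != model$n_in) {
    abort("x must be n_in x n_samples.", class = "emoselect_cnn_error")
  }
  n_lev <- nlevels(y)
  if ((model$head == "sigmoid_binary") != (n_lev == 2)) {
    abort("Label arity does not match the model head.",
          class = "emoselect_cnn_error")
  }
  model$class_levels <- levels(y)
  opt <- make_optimizer(resolve_optimizer(model), model$config, model)
  n <- ncol(x)
  bs <- model$config$batch_size
  n_epochs <- epochs %||% model$config$epochs
  y_num <- as.integer(y)
  Y_onehot <- NULL
  if (model$head != "sigmoid_binary") {
    Y_onehot <- matrix(0, n_lev, n)
    Y_onehot[cbind(y_num, seq_len(n))] <- 1
  }
  hist <- vector("list", n_epochs)
  for (ep in seq_len(n_epochs)) {
    res <- local_seed(child_seed(seed, ep), {
      ord <- sample.int(n)
      tot_loss <- 0
      tot_correct <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        Xb <- x[, idx, drop = FALSE]
        fw <- model_forward(model, Xb, training = TRUE)
        model <- fw$model # running BN stats
        B <- length(idx)
        if (model$head == "sigmoid_binary") {
          yb <- (y_num[idx] == 2) + 0
          loss <- binary_ce(yb, fw$out)
          dlogits <- (fw$out - matrix(yb, 1)) / B
          pred <- (fw$out > 0.5) + 1
        } else {
          Yb <- Y_onehot[, idx, drop = FALSE]
          loss <- categorical_ce(Yb, fw$out)
          dlogits <- (fw$out - Yb) / B
          pred <- apply(fw$out, 2, which.max)
        }
        if (!is.finite(loss)) {
          abort(paste0("Non-finite loss at epoch ", ep,
                       " (exploding update or bad input scaling)."),
                class = "emoselect_cnn_error")
        }
        grads <- model_backward(model, fw, dlogits)
        model <- opt(model, grads)
        tot_loss <- tot_loss + loss * B
        tot_correct <- tot_correct + sum(pred == y_num[idx])
      }
      list(model = model, loss = tot_loss / n, acc = tot_correct / n)
    })
    model <- res$model
    row <- tibble::tibble(epoch = ep, loss = res$loss,
                          accuracy = res$acc)
    if (!is.null(validation)) {
      pv <- predict(model, validation$x, type = "prob")
      yv <- factor(validation$y, levels = model$class_levels)
      if (model$head == "sigmoid_binary") {
        row$val_loss <- binary_ce((as.integer(yv) == 2) + 0, pv[2, ])
      } else {
        Yv <- matrix(0, n_lev, length(yv))
        Yv[cbind(as.integer(yv), seq_along(yv))] <- 1
        row$val_loss <- categorical_ce(Yv, pv)
      }
      row$val_accuracy <-
        mean(model$class_levels[apply(pv, 2, which.max)] ==
               as.character(yv))
    }
    hist[[ep]] <- row
  }
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Predict from a fitted 1D-CNN
#'
#' @param object A trained `cnn_model`.
#' @param x Input matrix, `n_in` x n_samples.
#' @param type `"class"` for hard labels, `"prob"` for a classes x
#'   n_samples probability matrix (binary models return both class
#'   rows).
#' @param ... Unused.
#' @return Factor of predictions or a probability matrix.
#' @export
predict.cnn_model <- function(object, x, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  fw <- model_forward(object, x, training = FALSE)
  levs <- object$class_levels %||%
    as.character(seq_len(object$n_classes))
  probs <- if (object$head == "sigmoid_binary") {
    rbind(1 - fw$out, fw$out)
  } else {
    fw$out
  }
  rownames(probs) <- levs
  if (type == "prob") return(probs)
  factor(levs[apply(probs, 2, which.max)], levels = levs)
}

#' @describeIn train Per-epoch training history of a fitted model.
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @export
tidy.cnn_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = double(),
                                accuracy = double())
}

#' @describeIn train One-row model summary.
#' @export
glance.cnn_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs_trained = nrow(h),
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_accuracy = if (nrow(h)) h$accuracy[nrow(h)] else NA_real_,
    optimizer = resolve_optimizer(x),
    head = x$head
  )
}

#' Grid search over CNN hyperparameters
#'
#' Exhaustive (or budget-capped) search over a grid of configuration
#' values, scoring each candidate by validation accuracy after
#' training; ties resolve toward the smaller parameter count.
#'
#' @param x_train,y_train Training inputs/labels.
#' @param x_val,y_val Validation inputs/labels.
#' @param space Named list of vectors of candidate values for
#'   [model_config()] fields (vector-valued fields like `filters` are
#'   given as lists of vectors).
#' @param budget Maximum number of candidates trained; a larger grid
#'   is subsampled deterministically under `seed`.
#' @param base Baseline [model_config()] supplying unsearched fields.
#' @param epochs Training epochs per candidate (override).
#' @param seed Integer seed.
#' @return List with `best_config` and a `results` tibble (one row per
#'   candidate: the searched values, `val_accuracy`, `n_parameters`).
#' @export
grid_search <- function(x_train, y_train, x_val, y_val, space,
                        budget = Inf, base = model_config(),
                        epochs = NULL, seed = 1L) {
  stopifnot(length(space) >= 1, !is.null(names(space)))
  space <- lapply(space, function(v) if (is.list(v)) v else as.list(v))
  grid <- expand.grid(lapply(space, seq_along))
  if (nrow(grid) == 0) {
    abort("Empty hyperparameter grid.", class = "emoselect_cnn_error")
  }
  if (nrow(grid) > budget) {
    keep <- local_seed(seed, sample.int(nrow(grid), budget))
    grid <- grid[sort(keep), , drop = FALSE]
  }
  n_lev <- nlevels(droplevels(as.factor(y_train)))
  rows <- vector("list", nrow(grid))
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    vals <- lapply(names(space), function(nm) {
      space[[nm]][[grid[r, nm]]]
    })
    names(vals) <- names(space)
    cfg_args <- modifyList(unclass(base), vals)
    cfg <- do.call(model_config, cfg_args)
    mdl <- build_model(cfg, n_in = nrow(x_train), n_classes = n_lev,
                       seed = child_seed(seed, r))
    mdl <- train(mdl, x_train, y_train, epochs = epochs,
                 seed = child_seed(seed, r))
    acc <- mean(predict(mdl, x_val) == factor(y_val,
                                              levels = mdl$class_levels))
    np <- n_parameters(mdl)
    rows[[r]] <- tibble::tibble(
      candidate = r,
      !!!lapply(vals, function(v) {
        if (length(v) > 1) paste(v, collapse = ",") else v
      }),
      val_accuracy = acc, n_parameters = np
    )
    if (is.null(best) || acc > best$acc ||
        (acc == best$acc && np < best$np)) {
      best <- list(cfg = cfg, acc = acc, np = np)
    }
  }
  list(best_config = best$cfg, results = dplyr::bind_rows(rows))
}
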