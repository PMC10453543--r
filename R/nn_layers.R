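# Internal 1D-CNN layer primitives.
#
# Activations flow through the network as C x (L*B) matrices: C filter
# channels, columns grouped batch-element-major (column (b-1)*L + t is
# time step t of element b). Convolutions use same-padding and are
# evaluated as a tap-shifted gather plus one GEMM per layer, so all
# heavy lifting is BLAS.

conv_cols <- function(L, B, k, Lp) {
  # column indices into the padded C x (Lp*B) matrix for each tap
  lapply(seq_len(k), function(tap) {
    as.vector(outer(seq(tap, L + tap - 1), (seq_len(B) - 1) * Lp, "+"))
  })
}

conv1d_forward <- function(M, W, b, k, L, B) {
  if (k == 1) {
    return(list(Z = W %*% M + b, M = M, k1 = TRUE))
  }
  C <- nrow(M)
  pad <- (k - 1) %/% 2
  Lp <- L + k - 1
  Mp <- matrix(0, C, Lp * B)
  keep <- as.vector(outer(seq(pad + 1, pad + L), (seq_len(B) - 1) * Lp,
                          "+"))
  Mp[, keep] <- M
  cols <- conv_cols(L, B, k, Lp)
  # per-tap GEMM accumulation; avoids materializing the full im2col
  # matrix (k times the activation size)
  Z <- W[, seq_len(C), drop = FALSE] %*% Mp[, cols[[1]], drop = FALSE]
  for (tap in seq_len(k)[-1]) {
    Z <- Z + W[, ((tap - 1) * C + 1):(tap * C), drop = FALSE] %*%
      Mp[, cols[[tap]], drop = FALSE]
  }
  Z <- Z + b
  list(Z = Z, Mp = Mp, keep = keep, cols = cols, Lp = Lp, k1 = FALSE)
}

conv1d_backward <- function(dZ, cache, W, k, L, B) {
  db <- rowSums(dZ)
  if (isTRUE(cache$k1)) {
    return(list(dW = tcrossprod(dZ, cache$M), db = db,
                dM = crossprod(W, dZ)))
  }
  Cin <- ncol(W) / k
  dW <- matrix(0, nrow(W), ncol(W))
  dMp <- matrix(0, Cin, cache$Lp * B)
  for (tap in seq_len(k)) {
    idx <- cache$cols[[tap]]
    block <- ((tap - 1) * Cin + 1):(tap * Cin)
    dW[, block] <- tcrossprod(dZ, cache$Mp[, idx, drop = FALSE])
    dMp[, idx] <- dMp[, idx] + crossprod(W[, block, drop = FALSE], dZ)
  }
  list(dW = dW, db = db, dM = dMp[, cache$keep, drop = FALSE])
}

bn_forward <- function(M, gamma, beta, running, training, eps = 1e-5,
                       momentum = 0.9) {
  if (training) {
    mu <- rowMeans(M)
    v <- rowMeans((M - mu)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  Xhat <- (M - mu) * inv_sd
  list(Z = gamma * Xhat + beta, Xhat = Xhat, inv_sd = inv_sd,
       running = running)
}

bn_backward <- function(dZ, cache, gamma) {
  Xhat <- cache$Xhat
  n <- ncol(dZ)
  dgamma <- rowSums(dZ * Xhat)
  dbeta <- rowSums(dZ)
  dXhat <- dZ * gamma
  dM <- cache$inv_sd *
    (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat))
  list(dM = dM, dgamma = dgamma, dbeta = dbeta)
}

#' Convolutional-layer activation function
#'
#' `"standard_relu"` is the rectifier `max(0, a)`; `"eq6_softplus"` is
#' the smooth variant `ln(1 + e^a)`, numerically stabilized as
#' `max(a, 0) + log1p(exp(-|a|))` so large magnitudes neither overflow
#' nor underflow.
#'
#' @param a Numeric vector/matrix of pre-activations.
#' @param variant `"standard_relu"` or `"eq6_softplus"`.
#' @return Activations, same shape as `a`.
#' @examples
#' activation(c(-3, 0, 50), "eq6_softplus")
#' @export
activation <- function(a, variant = c("standard_relu", "eq6_softplus")) {
  variant <- match.arg(variant)
  if (variant == "standard_relu") {
    a * (a > 0)
  } else {
    pmax(a, 0) + log1p(exp(-abs(a)))
  }
}

activation_grad <- function(a, variant) {
  if (variant == "standard_relu") {
    (a > 0) + 0
  } else {
    1 / (1 + exp(-a)) # d/da softplus = sigmoid
  }
}

avgpool2_forward <- function(M, L, B) {
  # average pooling, size 2 stride 2 along time
  odd <- as.vector(outer(seq(1, L, by = 2), (seq_len(B) - 1) * L, "+"))
  (M[, odd, drop = FALSE] + M[, odd + 1, drop = FALSE]) / 2
}

avgpool2_backward <- function(dZ, L, B) {
  C <- nrow(dZ)
  dM <- matrix(0, C, L * B)
  odd <- as.vector(outer(seq(1, L, by = 2), (seq_len(B) - 1) * L, "+"))
  dM[, odd] <- dZ / 2
  dM[, odd + 1] <- dZ / 2
  dM
}

dropout_mask <- function(dim1, dim2, p) {
  # inverted dropout: scale retained units by 1/(1-p) at train time
  matrix((runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}

flatten_forward <- function(M, C, L, B) {
  matrix(M, nrow = C * L, ncol = B)
}

unflatten_backward <- function(dX, C, L, B) {
  matrix(dX, nrow = C, ncol = L * B)
}
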