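#' Build the graph underlying graph-EMD
#'
#' Two constructions. `"temporal"`: a path graph over time samples,
#' applied per channel, which reduces graph EMD to a classical
#' (linear-envelope) EMD and is the fast default for augmentation.
#' `"product"`: the Cartesian product of a k-nearest-neighbour
#' Gaussian-kernel electrode graph (unit-sphere 10-20 coordinates,
#' kernel width = median neighbour distance) with the temporal path
#' graph, coupling channels spatially.
#'
#' @param n_samples Number of time samples per channel.
#' @param mode `"temporal"` or `"product"`.
#' @param montage A `montage` from [standard_1020_montage()]; required
#'   (and fully resolved) for product mode.
#' @param knn Spatial neighbours per electrode in product mode.
#' @return A `signal_graph`: sparse adjacency `A` and Laplacian `L`
#'   (row sums 0), vertex layout `dims` = c(channels, samples), and a
#'   construction descriptor.
#' @export
build_signal_graph <- function(n_samples, mode = c("temporal", "product"),
                               montage = NULL, knn = 4) {
  mode <- match.arg(mode)
  At <- path_adjacency(n_samples)
  if (mode == "temporal") {
    A <- At
    dims <- c(1L, as.integer(n_samples))
    descriptor <- list(mode = "temporal")
  } else {
    if (is.null(montage)) {
      abort("Product mode needs a montage.",
            class = "emoselect_graph_error")
    }
    if (any(!montage$resolved)) {
      abort(paste0("Unresolved electrodes in product mode: ",
                   paste(montage$channel[!montage$resolved],
                         collapse = ", ")),
            class = "emoselect_graph_error")
    }
    As <- spatial_knn_adjacency(montage, knn)
    n_ch <- nrow(montage)
    # channel-major vectorization: vertex (ch, t) -> (ch-1)*T + t
    A <- Matrix::kronecker(As, Matrix::Diagonal(n_samples)) +
      Matrix::kronecker(Matrix::Diagonal(n_ch), At)
    dims <- c(n_ch, as.integer(n_samples))
    descriptor <- list(mode = "product", knn = knn,
                       channels = montage$channel)
  }
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  structure(list(A = methods::as(A, "CsparseMatrix"),
                 L = methods::as(L, "CsparseMatrix"),
                 dims = dims, descriptor = descriptor),
            class = "signal_graph")
}

path_adjacency <- function(n) {
  if (n < 2) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                         dims = c(n, n)))
  i <- seq_len(n - 1)
  Matrix::sparseMatrix(i = c(i, i + 1), j = c(i + 1, i),
                       x = 1, dims = c(n, n))
}

# Symmetrized k-NN electrode graph with Gaussian kernel weights,
# bandwidth = median distance to the retained neighbours.
spatial_knn_adjacency <- function(montage, knn) {
  P <- as.matrix(montage[, c("x", "y", "z")])
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  A <- matrix(0, n, n)
  keep_d <- c()
  for (i in seq_len(n)) {
    nb <- setdiff(order(D[i, ]), i)[seq_len(min(knn, n - 1))]
    A[i, nb] <- 1
    keep_d <- c(keep_d, D[i, nb])
  }
  A <- pmax(A, t(A)) # symmetrize (union of neighbourhoods)
  sigma <- stats::median(keep_d)
  W <- exp(-D^2 / (2 * sigma^2)) * A
  Matrix::Matrix(W, sparse = TRUE)
}
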