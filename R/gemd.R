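#' Graph empirical mode decomposition of one epoch
#'
#' Iterative sifting on a graph: graph-neighbourhood extrema (a vertex
#' is a maximum/minimum iff its value strictly exceeds/undercuts all
#' neighbours; plateaus are not extrema), upper and lower envelopes by
#' Laplacian-regularized harmonic interpolation through the extrema
#' (the graph analogue of spline envelopes), mean-envelope subtraction
#' until the normalized squared change between sift iterations drops
#' below `sd_stop` (capped at `max_sift` iterations). Each extracted
#' component is one graph intrinsic mode function (IMF); extraction
#' repeats on the residue until `max_imfs` IMFs are found or the
#' residue has fewer than two maxima or two minima. The IMFs plus the
#' residual reconstruct the input to numerical precision.
#'
#' @param x Numeric matrix (channels x samples). In temporal mode each
#'   channel is decomposed independently on the path graph; in product
#'   mode the whole epoch is one signal on the product graph.
#' @param graph A [build_signal_graph()] whose sample count matches
#'   `ncol(x)` (and channel count `nrow(x)` for product mode).
#' @param max_imfs Maximum number of IMFs (default 5).
#' @param sd_stop Sifting stop threshold on the normalized squared
#'   change (default 0.2).
#' @param max_sift Cap on sift iterations per IMF (default 10).
#' @param class_label Optional class label inherited by the
#'   decomposition (and so by any epoch synthesized from it).
#' @return A `graph_imf_decomposition`: list of IMF matrices (possibly
#'   empty), `residual` matrix, `n_imfs`, `class_label`.
#' @export
decompose <- function(x, graph, max_imfs = 5, sd_stop = 0.2,
                      max_sift = 10, class_label = NULL) {
  stopifnot(inherits(graph, "signal_graph"))
  x <- as.matrix(x)
  if (graph$dims[1] == 1) {
    if (ncol(x) != graph$dims[2]) {
      abort("Signal length does not match the graph.",
            class = "emoselect_graph_error")
    }
    per_ch <- lapply(seq_len(nrow(x)), function(ch) {
      sift_signal(x[ch, ], graph$A, max_imfs, sd_stop, max_sift,
                  is_path = TRUE)
    })
    n_imfs <- max(vapply(per_ch, function(d) length(d$imfs), 0L))
    imfs <- lapply(seq_len(n_imfs), function(j) {
      do.call(rbind, lapply(per_ch, function(d) {
        if (j <= length(d$imfs)) d$imfs[[j]] else rep(0, ncol(x))
      }))
    })
    residual <- do.call(rbind, lapply(per_ch, function(d) d$residual))
  } else {
    if (!all(dim(x) == graph$dims)) {
      abort("Epoch shape does not match the product graph.",
            class = "emoselect_graph_error")
    }
    v <- as.vector(t(x)) # channel-major: (ch-1)*T + t
    d <- sift_signal(v, graph$A, max_imfs, sd_stop, max_sift)
    imfs <- lapply(d$imfs, function(im) {
      matrix(im, nrow(x), ncol(x), byrow = TRUE)
    })
    residual <- matrix(d$residual, nrow(x), ncol(x), byrow = TRUE)
    n_imfs <- length(imfs)
  }
  structure(
    list(imfs = imfs, residual = residual, n_imfs = as.integer(n_imfs),
         class_label = class_label, dims = dim(x)),
    class = "graph_imf_decomposition"
  )
}

# Core sifting loop on a vector signal over adjacency A. For path
# graphs (`is_path`) the extrema test vectorizes and harmonic
# interpolation reduces exactly to linear interpolation between
# anchors with constant extension beyond the outermost ones.
sift_signal <- function(v, A, max_imfs, sd_stop, max_sift,
                        is_path = FALSE) {
  extrema <- if (is_path) path_extrema else function(h) graph_extrema(h, A)
  interp <- if (is_path) {
    function(h, anchors) {
      stats::approx(anchors, h[anchors], xout = seq_along(h),
                    rule = 2)$y
    }
  } else {
    function(h, anchors) harmonic_interpolate(h, anchors, A)
  }
  imfs <- list()
  residue <- v
  for (k in seq_len(max_imfs)) {
    ext <- extrema(residue)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    h <- residue
    for (it in seq_len(max_sift)) {
      ext_h <- extrema(h)
      if (length(ext_h$maxima) < 2 || length(ext_h$minima) < 2) break
      upper <- interp(h, ext_h$maxima)
      lower <- interp(h, ext_h$minima)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum((h_new - h)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_crit < sd_stop) break
    }
    imfs[[k]] <- h
    residue <- residue - h
  }
  list(imfs = imfs, residual = residue)
}

# Strict local extrema on a path graph, vectorized. Endpoints have a
# single neighbour; plateau ties are not extrema.
path_extrema <- function(v) {
  n <- length(v)
  if (n < 2) return(list(maxima = integer(), minima = integer()))
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  maxima <- which(v > left & v > right)
  left <- c(Inf, v[-n])
  right <- c(v[-1], Inf)
  minima <- which(v < left & v < right)
  list(maxima = maxima, minima = minima)
}

# Strict local extrema of a graph signal: value strictly above (below)
# every neighbour; plateau ties are not extrema.
graph_extrema <- function(v, A) {
  A <- methods::as(A, "CsparseMatrix")
  n <- length(v)
  is_max <- rep(TRUE, n)
  is_min <- rep(TRUE, n)
  has_nb <- rep(FALSE, n)
  p <- A@p
  idx <- A@i + 1L
  for (j in seq_len(n)) {
    nb <- idx[(p[j] + 1):p[j + 1]]
    if (p[j] == p[j + 1]) { is_max[j] <- is_min[j] <- FALSE; next }
    has_nb[j] <- TRUE
    mx <- max(v[nb]); mn <- min(v[nb])
    if (v[j] <= mx) is_max[j] <- FALSE
    if (v[j] >= mn) is_min[j] <- FALSE
  }
  list(maxima = which(is_max & has_nb), minima = which(is_min & has_nb))
}

# Envelope through the anchor vertices: minimize the Laplacian
# quadratic form subject to equality at anchors (harmonic
# interpolation), i.e. solve L[free, free] u = -L[free, anchor] v_a.
harmonic_interpolate <- function(v, anchors, A) {
  n <- length(v)
  u <- v
  free <- setdiff(seq_len(n), anchors)
  if (length(free) == 0) return(v)
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  rhs <- -L[free, anchors, drop = FALSE] %*% v[anchors]
  Lff <- L[free, free, drop = FALSE] +
    Matrix::Diagonal(length(free), 1e-12)
  u[free] <- as.vector(Matrix::solve(Lff, rhs))
  u
}
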