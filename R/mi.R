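#' Joint distribution of two discrete variables
#'
#' @param a,b Vectors of equal length (factors or discrete values), or
#'   give `probs` directly as a matrix of joint probabilities.
#' @param probs Optional joint probability matrix (rows = levels of A,
#'   columns = levels of B); must be non-negative and sum to 1.
#' @return A `joint_distribution`: list with `probs` and marginals
#'   `pa`, `pb`.
#' @export
joint_distribution <- function(a = NULL, b = NULL, probs = NULL) {
  if (is.null(probs)) {
    stopifnot(length(a) == length(b), length(a) > 0)
    probs <- table(a, b) / length(a)
    probs <- matrix(as.numeric(probs), nrow = nrow(probs),
                    dimnames = dimnames(probs))
  }
  probs <- as.matrix(probs)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("Joint probabilities must be non-negative and sum to 1.",
          class = "emoselect_mi_error")
  }
  structure(
    list(probs = probs, pa = rowSums(probs), pb = colSums(probs)),
    class = "joint_distribution"
  )
}

#' Mutual information of a joint distribution
#'
#' Plug-in mutual information
#' `sum_ab P(a,b) ln( P(a,b) / (P(a) P(b)) )` in nats; cells with zero
#' joint probability contribute zero.
#'
#' @param joint A [joint_distribution()], or anything coercible via
#'   `joint_distribution(probs = .)`.
#' @return Non-negative scalar (nats).
#' @examples
#' mutual_information(joint_distribution(probs = diag(2) / 2)) # ln 2
#' @export
mutual_information <- function(joint) {
  if (!inherits(joint, "joint_distribution")) {
    joint <- joint_distribution(probs = joint)
  }
  p <- joint$probs
  outer_p <- outer(joint$pa, joint$pb)
  nz <- p > 0
  max(sum(p[nz] * log(p[nz] / outer_p[nz])), 0)
}

# Plug-in MI between two discrete vectors (nats).
mi_discrete <- function(a, b) {
  mutual_information(joint_distribution(a, b))
}

# Class-conditional MI: sum_c P(c) * MI(a, b | C = c), plug-in on the
# per-class joints.
cmi_discrete <- function(a, b, cls) {
  cls <- as.factor(cls)
  total <- 0
  for (c_ in levels(cls)) {
    idx <- cls == c_
    if (sum(idx) < 2) next
    total <- total + mean(idx) * mi_discrete(a[idx], b[idx])
  }
  total
}

# Equal-frequency discretization of a numeric vector into n_bins
# symbols (1..n_bins); -Inf values (degenerate all-zero windows) land
# in bin 1.
discretize_ef <- function(x, n_bins = 4) {
  finite <- x[is.finite(x)]
  if (length(unique(finite)) <= 1) return(rep(1L, length(x)))
  e <- quantile(finite, probs = seq(0, 1, length.out = n_bins + 1),
                names = FALSE, type = 7)
  inner <- unique(e[2:n_bins])
  sym <- findInterval(x, inner, left.open = FALSE) + 1L
  sym[!is.finite(x)] <- 1L
  sym
}
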