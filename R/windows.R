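#' Non-overlapping window spans for an epoch set
#'
#' Splits each trial into consecutive windows of
#' `window_seconds * sampling_rate` samples. Spans are half-open
#' `[start, end)` with 0-based sample positions, tagging every window
#' with its place in the original signal; a trailing partial window is
#' discarded.
#'
#' @param epochs An [epoch_set()].
#' @param window_seconds Window length in seconds (default 2).
#' @param overlap Fractional overlap between consecutive windows; the
#'   default 0 gives the non-overlapping segmentation used throughout.
#' @return Tibble with columns `window` (1-based ordinal), `start`,
#'   `end`; attribute `window_samples` records the span length.
#' @export
segment_windows <- function(epochs, window_seconds = 2, overlap = 0) {
  stopifnot(inherits(epochs, "epoch_set"),
            overlap >= 0, overlap < 1)
  n <- ncol(epochs$data[[1]])
  win_n <- as.integer(round(window_seconds * epochs$sampling_rate))
  if (win_n > n) {
    abort("Window longer than the trial.",
          class = "emoselect_window_error")
  }
  stride <- max(1L, as.integer(round(win_n * (1 - overlap))))
  starts <- seq(0L, n - win_n, by = stride)
  out <- tibble::tibble(
    window = seq_along(starts),
    start = as.integer(starts),
    end = as.integer(starts + win_n)
  )
  attr(out, "window_samples") <- win_n
  attr(out, "window_seconds") <- window_seconds
  out
}

#' Differential entropy of one signal window
#'
#' `h = 1/2 log(P) + 1/2 log(2 pi e N)` (natural log), where `P` is the
#' window's average energy (mean squared amplitude, standing in for the
#' variance) and `N` the window length in samples. An all-zero window
#' has `P = 0` and returns `-Inf`, which downstream ranking excludes
#' with a warning.
#'
#' @param x Numeric vector, the window's samples.
#' @param N Window length; defaults to `length(x)`.
#' @return Scalar differential entropy (nats).
#' @examples
#' window_de(rep(1, 256)) # P = 1, so h = 0.5 * log(2*pi*e*256)
#' @export
window_de <- function(x, N = length(x)) {
  stopifnot(N >= 1)
  P <- mean(x^2)
  if (P == 0) return(-Inf)
  0.5 * log(P) + 0.5 * log(2 * pi * exp(1) * N)
}

#' Per-window differential-entropy features
#'
#' Applies [window_de()] to every (trial, channel, window) cell of the
#' non-overlapping segmentation.
#'
#' @inheritParams segment_windows
#' @return A `window_feature_matrix` tibble: `trial`, `channel`,
#'   `window`, `start`, `end`, `de`.
#' @export
window_features <- function(epochs, window_seconds = 2) {
  spans <- segment_windows(epochs, window_seconds)
  win_n <- attr(spans, "window_samples")
  n_tr <- n_trials(epochs)
  n_ch <- length(epochs$channel_names)
  # mean energy per window via a single column-sum reshape per trial
  res <- purrr::map(seq_len(n_tr), function(i) {
    m <- epochs$data[[i]]
    de <- matrix(NA_real_, n_ch, nrow(spans))
    for (w in seq_len(nrow(spans))) {
      span <- (spans$start[w] + 1):spans$end[w]
      seg <- m[, span, drop = FALSE]
      P <- rowMeans(seg^2)
      de[, w] <- ifelse(P == 0, -Inf,
                        0.5 * log(P) + 0.5 * log(2 * pi * exp(1) * win_n))
    }
    tibble::tibble(
      trial = i,
      channel = rep(epochs$channel_names, times = nrow(spans)),
      window = rep(spans$window, each = n_ch),
      start = rep(spans$start, each = n_ch),
      end = rep(spans$end, each = n_ch),
      de = as.vector(de)
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "window_samples") <- win_n
  attr(out, "window_seconds") <- window_seconds
  class(out) <- c("window_feature_matrix", class(out))
  out
}

#' Extract the raw samples of selected window spans
#'
#' Concatenates, per channel and trial, the raw samples of the selected
#' spans in selection order, yielding the reduced epochs fed to the
#' classifier. Per-channel output length is exactly
#' `k * window_samples`.
#'
#' @param epochs An [epoch_set()].
#' @param spans Tibble with `start`/`end` columns (0-based, half-open),
#'   e.g. from [select_top_windows()]; rows in selection order.
#' @return An [epoch_set()] of reduced trials (labels preserved).
#' @export
map_to_raw <- function(epochs, spans) {
  stopifnot(inherits(epochs, "epoch_set"))
  spans <- dplyr::distinct(tibble::as_tibble(spans),
                           .data$start, .data$end)
  n <- ncol(epochs$data[[1]])
  if (any(spans$start < 0) || any(spans$end > n) ||
      any(spans$end <= spans$start)) {
    abort("Spans out of trial bounds.", class = "emoselect_window_error")
  }
  o <- order(spans$start)
  if (any(spans$end[o][-nrow(spans)] > spans$start[o][-1])) {
    abort("Overlapping spans are not allowed.",
          class = "emoselect_window_error")
  }
  idx <- unlist(purrr::map2(spans$start, spans$end,
                            function(s, e) (s + 1):e))
  epoch_set(
    lapply(epochs$data, function(m) m[, idx, drop = FALSE]),
    epochs$channel_names, epochs$sampling_rate, epochs$meta,
    c(epochs$metadata, list(reduced = TRUE))
  )
}
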