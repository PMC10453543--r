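#' Discretize epochs into per-channel amplitude-bin symbols
#'
#' Equal-frequency bin edges are computed per channel over all trials
#' pooled, so each bin holds (up to ties) the same share of the
#' channel's samples. Every sample maps to exactly one bin symbol.
#' Constant channels collapse into a single occupied bin and are
#' flagged, not rejected.
#'
#' @param epochs An [epoch_set()].
#' @param n_bins Number of amplitude bins (>= 2). The default 32 gives
#'   the amplitude resolution needed to separate class-specific
#'   oscillatory-burst tails from the noise floor; coarse binnings can
#'   saturate (every class occupies every bin).
#' @param keep_symbols Keep the per-trial symbol matrices (set to
#'   `FALSE` to retain only the bin-count summaries, which is all the
#'   channel scoring needs; saves memory on large sets).
#' @return A `discretized_epochs` object: per-trial integer symbol
#'   matrices (unless `keep_symbols = FALSE`) plus bin edges, bin
#'   counts per (bin, trial, channel), and a `constant_channels` flag
#'   vector.
#' @export
discretize <- function(epochs, n_bins = 32, keep_symbols = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"), is_count(n_bins), n_bins >= 2)
  n_ch <- length(epochs$channel_names)
  n_tr <- n_trials(epochs)
  n_samp <- vapply(epochs$data, ncol, 0L)
  edges <- vector("list", n_ch)
  constant <- logical(n_ch)
  # counts[bin, trial, channel]: bin-occupancy histogram, the sufficient
  # statistic for the channel relevance score
  counts <- array(0L, c(n_bins, n_tr, n_ch))
  symbols <- if (keep_symbols) {
    lapply(seq_len(n_tr), function(i) {
      m <- epochs$data[[i]]
      matrix(0L, nrow(m), ncol(m))
    })
  }
  trial_of <- rep.int(seq_len(n_tr), n_samp)
  for (ch in seq_len(n_ch)) {
    pooled <- unlist(lapply(epochs$data, function(m) m[ch, ]),
                     use.names = FALSE)
    e <- quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1),
                  names = FALSE, type = 7)
    inner <- e[2:n_bins]
    constant[ch] <- length(unique(e)) == 1
    edges[[ch]] <- e
    sym <- findInterval(pooled, inner, left.open = FALSE) + 1L
    # one tabulate over (trial, bin) pairs instead of a per-trial loop
    counts[, , ch] <- tabulate((trial_of - 1L) * n_bins + sym,
                               nbins = n_bins * n_tr)
    if (keep_symbols) {
      off <- c(0L, cumsum(n_samp))
      for (i in seq_len(n_tr)) {
        symbols[[i]][ch, ] <- sym[(off[i] + 1):off[i + 1]]
      }
    }
  }
  structure(
    list(symbols = symbols, bin_edges = edges, n_bins = n_bins,
         counts = counts, constant_channels = constant,
         channel_names = epochs$channel_names),
    class = "discretized_epochs"
  )
}

# Relevance score of one channel for one class from bin-count matrix
# cnt (n_bins x n_trials): the class symbol set is the union of bins
# occupied by class trials; each trial contributes -log2 of the share
# of its samples falling in that set; zero shares are floored at
# 1/(n_samples + 1) to keep the logarithm finite.
score_from_counts <- function(cnt, class_idx) {
  in_class_bins <- rowSums(cnt[, class_idx, drop = FALSE]) > 0
  n_per_trial <- colSums(cnt)
  shared <- colSums(cnt[in_class_bins, , drop = FALSE])
  ratio <- shared / n_per_trial
  ratio <- pmax(ratio, 1 / (n_per_trial + 1))
  -mean(log2(ratio))
}

#' Differential-entropy relevance score of one channel for one class
#'
#' Implements the channel relevance measure: with `U` the universe of
#' all trials and `x_C` the set of amplitude-bin symbols occupied by
#' the class-`class_c` trials on this channel, each trial `z` in `U`
#' contributes `-log2(|x_C intersect x_P| / |x_P|)` where `x_P` is the
#' multiset of `z`'s symbols, i.e. minus the log2 fraction of `z`'s
#' samples whose symbol the class also occupies, averaged over `U`.
#' Scores are >= 0; a channel whose every trial stays inside the class
#' symbol set scores exactly 0.
#'
#' @param disc A `discretized_epochs` from [discretize()].
#' @param labels Factor of per-trial class labels.
#' @param channel Channel name or index.
#' @param class_c Class label to score against.
#' @return Non-negative scalar score (bits).
#' @export
channel_class_score <- function(disc, labels, channel, class_c) {
  stopifnot(inherits(disc, "discretized_epochs"))
  labels <- as.factor(labels)
  if (!class_c %in% labels) {
    abort(paste0("Class '", class_c, "' absent from labels."),
          class = "emoselect_score_error")
  }
  ch <- if (is.character(channel)) {
    match(channel, disc$channel_names)
  } else {
    as.integer(channel)
  }
  if (is.na(ch) || ch < 1 || ch > length(disc$channel_names)) {
    abort("Unknown channel.", class = "emoselect_score_error")
  }
  score_from_counts(disc$counts[, , ch], which(labels == class_c))
}

#' Score every channel against every class
#'
#' @param epochs An [epoch_set()] (or a pre-computed
#'   `discretized_epochs`).
#' @param labels Factor of per-trial labels; alternatively give `task`
#'   to derive them from the epoch metadata via [epoch_labels()].
#' @param task Optional task name passed to [epoch_labels()].
#' @param n_bins Amplitude bins for [discretize()] (ignored when
#'   `epochs` is already discretized).
#' @return A `channel_score_table` tibble: one row per (channel, class)
#'   with the relevance `score`, plus each channel's `max_score` over
#'   classes; attribute `universe_size` records the trial count.
#' @export
score_channels <- function(epochs, labels = NULL, task = NULL,
                           n_bins = 32) {
  if (inherits(epochs, "epoch_set")) {
    if (is.null(labels)) {
      if (is.null(task)) {
        abort("Provide labels or task.", class = "emoselect_score_error")
      }
      labels <- epoch_labels(epochs, task)
    }
    disc <- discretize(epochs, n_bins, keep_symbols = FALSE)
  } else {
    disc <- epochs
    if (is.null(labels)) {
      abort("Provide labels when passing a discretized_epochs.",
            class = "emoselect_score_error")
    }
  }
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  out <- tidyr::expand_grid(channel = disc$channel_names,
                            class = classes)
  out$score <- purrr::map2_dbl(out$channel, out$class, function(ch, cl) {
    score_from_counts(disc$counts[, , match(ch, disc$channel_names)],
                      which(labels == cl))
  })
  out <- out |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(max_score = max(.data$score)) |>
    dplyr::ungroup()
  attr(out, "universe_size") <- length(labels)
  attr(out, "n_bins") <- disc$n_bins
  class(out) <- c("channel_score_table", class(out))
  out
}

#' Threshold a channel score table
#'
#' Keeps channels whose maximum score over classes reaches `threshold`,
#' ordered by descending score with ties broken by montage (input)
#' order. An empty result is returned with a warning, so the caller can
#' lower the threshold.
#'
#' @param table A `channel_score_table` from [score_channels()].
#' @param threshold Selection threshold (default 1.5).
#' @return Tibble with columns `channel`, `score` (max over classes).
#' @export
select_channels <- function(table, threshold = 1.5) {
  per_ch <- table |>
    dplyr::distinct(.data$channel, .data$max_score) |>
    dplyr::mutate(.order = dplyr::row_number()) |>
    dplyr::filter(.data$max_score >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$max_score), .data$.order) |>
    dplyr::transmute(channel = .data$channel, score = .data$max_score)
  if (nrow(per_ch) == 0) {
    warn("No channel reaches the threshold; returning an empty set.")
  }
  per_ch
}

#' Channels common to several per-dataset selections
#'
#' Intersects the channel selections of several datasets. If the
#' intersection exceeds `k`, the `k` channels with the best (lowest)
#' mean rank across selections are kept; if smaller than `k`, the
#' intersection is returned as-is with a warning.
#'
#' @param selections List of selections: tibbles from
#'   [select_channels()] (ranked) or plain character vectors.
#' @param k Target number of common channels (default 10).
#' @return Tibble with columns `channel`, `mean_rank`.
#' @export
common_channels <- function(selections, k = 10) {
  stopifnot(length(selections) >= 1)
  name_sets <- lapply(selections, function(s) {
    if (is.character(s)) s else s$channel
  })
  common <- Reduce(intersect, name_sets)
  if (length(name_sets) > 1 && all(lengths(name_sets) > 0)) {
    any_shared <- any(vapply(seq_along(name_sets)[-1], function(i) {
      length(intersect(name_sets[[1]], name_sets[[i]])) > 0
    }, TRUE))
    if (!any_shared && length(common) == 0) {
      abort("Selections share no channel names (disjoint name spaces).",
            class = "emoselect_score_error")
    }
  }
  ranks <- vapply(common, function(ch) {
    mean(vapply(name_sets, function(s) match(ch, s), 0))
  }, 0)
  out <- tibble::tibble(channel = common, mean_rank = ranks) |>
    dplyr::arrange(.data$mean_rank, .data$channel)
  if (nrow(out) > k) {
    out <- out[seq_len(k), ]
  } else if (nrow(out) < k) {
    warn(paste0("Only ", nrow(out), " common channels (requested ", k,
                ")."))
  }
  out
}
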