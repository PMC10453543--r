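#' DMIM objective for one candidate feature
#'
#' Decomposed mutual-information maximization score
#' `MI(Xi, C) - max_{Xs in S} MI(Xi, Xs) + max_{Xs in S} MI(Xi, Xs | C)`:
#' class relevance, minus the strongest inter-feature redundancy,
#' plus the strongest class-conditional redundancy. With an empty
#' selected set both maxima are 0 and the score reduces to the plain
#' relevance.
#'
#' @param xi Discretized candidate feature (integer/factor vector, one
#'   value per observation).
#' @param selected List of already-selected discretized features (may
#'   be empty).
#' @param cls Factor of class labels, same length as `xi`.
#' @return List with `score`, `relevance`, `redundancy`,
#'   `cond_redundancy`.
#' @export
dmim_score <- function(xi, selected, cls) {
  rel <- mi_discrete(xi, cls)
  if (length(selected) == 0) {
    return(list(score = rel, relevance = rel, redundancy = 0,
                cond_redundancy = 0))
  }
  red <- max(vapply(selected, function(xs) mi_discrete(xi, xs), 0))
  cred <- max(vapply(selected, function(xs) cmi_discrete(xi, xs, cls), 0))
  list(score = rel - red + cred, relevance = rel, redundancy = red,
       cond_redundancy = cred)
}

#' Greedy sequential-forward DMIM feature ranking
#'
#' Ranks per-window differential-entropy features by repeatedly
#' selecting the candidate maximizing the DMIM objective
#' ([dmim_score()]). Candidates are per-window variables: with the
#' default `"pooled"` granularity the DE values are averaged over
#' channels so every trial yields one observation per window (window
#' ordinals are then shared across trials); `"channel_window"` keeps
#' one candidate per (channel, window) pair. Continuous DE values are
#' discretized into `n_bins` equal-frequency bins before the plug-in
#' MI estimate. Ties in the argmax break toward the lower window
#' ordinal, making runs deterministic.
#'
#' Stopping: `"fixed_k"` selects exactly `k` features;
#' `"accuracy"` follows the accuracy-driven loop instead, monitoring a
#' nearest-centroid proxy classifier on a held-out third of trials and
#' stopping once adding a feature no longer improves validation
#' accuracy.
#'
#' @param features A `window_feature_matrix` from [window_features()].
#' @param labels Factor of per-trial class labels.
#' @param k Number of features to select (upper bound for the
#'   accuracy-driven rule).
#' @param stop Stopping rule, `"fixed_k"` or `"accuracy"`.
#' @param granularity `"pooled"` or `"channel_window"`.
#' @param n_bins Equal-frequency bins for MI estimation (default 4).
#' @return A `dmim_ranking` tibble in selection order: `step`,
#'   `window` (and `channel` if per-channel), `start`, `end`,
#'   `relevance`, `redundancy`, `cond_redundancy`, `score`, and the
#'   proxy `accuracy` trace when the accuracy rule is active.
#' @export
dmim_rank <- function(features, labels, k = 20,
                      stop = c("fixed_k", "accuracy"),
                      granularity = c("pooled", "channel_window"),
                      n_bins = 4) {
  stop <- match.arg(stop)
  granularity <- match.arg(granularity)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) {
    abort("Need at least two classes to rank features.",
          class = "emoselect_dmim_error")
  }
  if (granularity == "pooled") {
    wide <- features |>
      dplyr::group_by(.data$trial, .data$window, .data$start,
                      .data$end) |>
      dplyr::summarise(de = mean(.data$de), .groups = "drop")
    wide$candidate <- as.character(wide$window)
  } else {
    wide <- features |>
      dplyr::mutate(candidate = paste0(.data$channel, ":",
                                       .data$window))
  }
  cand_info <- wide |>
    dplyr::distinct(.data$candidate, .data$window, .data$start,
                    .data$end,
                    dplyr::across(dplyr::any_of("channel")))
  # observations = trials, ordered
  cand_info <- dplyr::arrange(cand_info, .data$window)
  X <- lapply(cand_info$candidate, function(cd) {
    v <- wide$de[wide$candidate == cd][order(wide$trial[wide$candidate ==
                                                          cd])]
    v
  })
  if (length(X) < 2) {
    abort("Need at least two candidate features.",
          class = "emoselect_dmim_error")
  }
  n_obs <- length(X[[1]])
  if (n_obs != length(labels)) {
    abort("labels length must equal the trial count.",
          class = "emoselect_dmim_error")
  }
  drop_inf <- vapply(X, function(v) all(!is.finite(v)), TRUE)
  if (any(drop_inf)) {
    warn(paste0(sum(drop_inf),
                " all-degenerate candidate(s) excluded from ranking."))
  }
  Xd <- lapply(X, discretize_ef, n_bins = n_bins)

  val_idx <- NULL
  if (stop == "accuracy") {
    # deterministic stratified hold-out: every 3rd trial per class
    ord <- order(as.integer(labels), seq_len(n_obs))
    val_idx <- sort(ord[seq(3, n_obs, by = 3)])
  }
  k <- min(k, sum(!drop_inf))
  selected <- integer()
  rows <- list()
  best_acc <- -Inf
  remaining <- which(!drop_inf)
  for (step in seq_len(k)) {
    scores <- vapply(remaining, function(j) {
      dmim_score(Xd[[j]], Xd[selected], labels)$score
    }, 0)
    pick <- remaining[which.max(scores)] # ties: lowest ordinal wins
    det <- dmim_score(Xd[[pick]], Xd[selected], labels)
    acc <- NA_real_
    if (stop == "accuracy") {
      acc <- centroid_proxy_accuracy(X, c(selected, pick), labels,
                                     val_idx)
      if (acc <= best_acc && step > 1) break
      best_acc <- max(best_acc, acc)
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    rows[[step]] <- dplyr::bind_cols(
      tibble::tibble(step = step),
      cand_info[pick, setdiff(names(cand_info), "candidate")],
      tibble::tibble(relevance = det$relevance,
                     redundancy = det$redundancy,
                     cond_redundancy = det$cond_redundancy,
                     score = det$score, accuracy = acc)
    )
    if (length(remaining) == 0) break
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "granularity") <- granularity
  attr(out, "n_bins") <- n_bins
  attr(out, "window_samples") <- attr(features, "window_samples")
  class(out) <- c("dmim_ranking", class(out))
  out
}

# Nearest-centroid classifier on the selected raw DE features,
# trained on the non-validation trials; cheap deterministic proxy for
# the accuracy-driven stopping loop.
centroid_proxy_accuracy <- function(X, sel, labels, val_idx) {
  M <- do.call(cbind, X[sel])
  train <- setdiff(seq_len(nrow(M)), val_idx)
  cents <- lapply(levels(labels), function(cl) {
    colMeans(M[intersect(train, which(labels == cl)), , drop = FALSE])
  })
  pred <- vapply(val_idx, function(i) {
    d <- vapply(cents, function(ct) sum((M[i, ] - ct)^2), 0)
    which.min(d)
  }, 0L)
  mean(levels(labels)[pred] == labels[val_idx])
}

#' Keep the top-k window spans of a DMIM ranking
#'
#' @param ranking A `dmim_ranking` from [dmim_rank()].
#' @param k Number of features to keep (default 20). Requesting more
#'   than available returns all with a warning; `k = 0` gives an empty
#'   span set.
#' @return Tibble of spans in selection order (`window`, `start`,
#'   `end`, plus `channel` for per-channel rankings).
#' @export
select_top_windows <- function(ranking, k = 20) {
  if (k > nrow(ranking)) {
    warn(paste0("Requested ", k, " spans but ranking has only ",
                nrow(ranking), "; returning all."))
    k <- nrow(ranking)
  }
  cols <- intersect(c("window", "channel", "start", "end"),
                    names(ranking))
  out <- ranking[seq_len(k), cols, drop = FALSE]
  tibble::as_tibble(out)
}
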