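#' Synthesize one artificial epoch from class-matched decompositions
#'
#' The artificial epoch is the sum over IMF slots of the j-th IMF of
#' the j-th contributing decomposition (first IMF from the first
#' contributor, second from the second, ...). A contributor with fewer
#' IMFs than its slot contributes a zero graph signal. All
#' contributors must carry the target class label: artificial epochs
#' are generated exclusively from IMFs of a single class.
#'
#' @param contributors Ordered list of `graph_imf_decomposition`
#'   objects, one per IMF slot.
#' @param class_c Class label of the synthesized epoch.
#' @return Numeric matrix (channels x samples) labelled `class_c` via
#'   attribute `class_label`.
#' @export
synthesize_epoch <- function(contributors, class_c) {
  stopifnot(length(contributors) >= 1,
            all(vapply(contributors, inherits, TRUE,
                       "graph_imf_decomposition")))
  cls <- vapply(contributors, function(d) {
    as.character(d$class_label %||% NA_character_)
  }, "")
  if (any(is.na(cls)) || any(cls != as.character(class_c))) {
    abort("All contributors must carry the target class label.",
          class = "emoselect_augment_error")
  }
  dims <- contributors[[1]]$dims
  out <- matrix(0, dims[1], dims[2])
  for (j in seq_along(contributors)) {
    d <- contributors[[j]]
    if (j <= d$n_imfs) out <- out + d$imfs[[j]]
    # else: missing IMF slot counts as a zero graph signal
  }
  attr(out, "class_label") <- class_c
  out
}

#' Class-conditional graph-EMD augmentation of an epoch set
#'
#' Generates `ratio * n_trials` artificial epochs with the original
#' class proportions preserved: for each artificial epoch of a class,
#' `max_imfs` contributor epochs are drawn uniformly without
#' replacement from that class, decomposed (each source epoch is
#' decomposed once and cached), and mixed with [synthesize_epoch()].
#' Classes with fewer than `max_imfs` epochs are skipped with a
#' warning. The result is the original set followed by the artificial
#' epochs, flagged `augmented = TRUE` in the metadata; each artificial
#' epoch inherits the label record of its first contributor. A
#' distributional guard checks that per-channel variances of the
#' artificial epochs stay within 1.5x the contributor range and logs
#' (but does not fail on) violations.
#'
#' @param epochs An [epoch_set()].
#' @param ratio Artificial-to-original ratio (default 1.0; 0 returns
#'   the input unchanged).
#' @param labels Optional factor of class labels; otherwise derived
#'   via `task` (or the `class` column).
#' @param task Optional task for [epoch_labels()].
#' @param mode Graph mode for [build_signal_graph()].
#' @param max_imfs IMF slots / contributors per synthesis (default 5).
#' @param montage Montage for product mode.
#' @param seed Integer seed; output is deterministic given it.
#' @return An [epoch_set()] with original and artificial trials;
#'   `metadata$augmentation_log` records the contributor indices of
#'   every artificial epoch.
#' @export
augment_dataset <- function(epochs, ratio = 1.0, labels = NULL,
                            task = NULL, mode = c("temporal", "product"),
                            max_imfs = 5, montage = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "epoch_set"), ratio >= 0)
  if (ratio == 0) return(epochs)
  if (is.null(labels)) {
    labels <- if (!is.null(task)) {
      epoch_labels(epochs, task)
    } else if ("class" %in% names(epochs$meta)) {
      factor(epochs$meta$class)
    } else {
      abort("Provide labels or task for class-conditional augmentation.",
            class = "emoselect_augment_error")
    }
  }
  labels <- droplevels(as.factor(labels))
  n <- n_trials(epochs)
  graph <- build_signal_graph(
    ncol(epochs$data[[1]]), mode,
    montage = montage %||%
      if (mode == "product") standard_1020_montage(epochs$channel_names),
    knn = 4
  )
  decomp_cache <- vector("list", n)
  get_decomp <- function(i) {
    if (is.null(decomp_cache[[i]])) {
      decomp_cache[[i]] <<- decompose(
        epochs$data[[i]], graph, max_imfs = max_imfs,
        class_label = as.character(labels[i])
      )
    }
    decomp_cache[[i]]
  }
  new_data <- list()
  new_meta <- list()
  log <- list()
  guard_violations <- 0L
  for (cl in levels(labels)) {
    members <- which(labels == cl)
    n_new <- round(ratio * length(members))
    if (n_new == 0) next
    if (length(members) < max_imfs) {
      warn(paste0("Class '", cl, "' has fewer than ", max_imfs,
                  " epochs; skipped in augmentation."))
      next
    }
    draws <- local_seed(child_seed(seed, match(cl, levels(labels))), {
      lapply(seq_len(n_new), function(j) sample(members, max_imfs))
    })
    for (j in seq_len(n_new)) {
      contrib <- draws[[j]]
      dec <- lapply(contrib, get_decomp)
      x <- synthesize_epoch(dec, cl)
      attr(x, "class_label") <- NULL
      v_new <- apply(x, 1, var)
      v_con <- matrix(
        vapply(contrib, function(i) apply(epochs$data[[i]], 1, var),
               numeric(nrow(x))),
        nrow = nrow(x)
      )
      lo <- apply(v_con, 1, min) / 1.5
      hi <- apply(v_con, 1, max) * 1.5
      if (any(v_new < lo | v_new > hi)) {
        guard_violations <- guard_violations + 1L
      }
      new_data[[length(new_data) + 1]] <- x
      m <- epochs$meta[contrib[1], , drop = FALSE]
      m$augmented <- TRUE
      new_meta[[length(new_meta) + 1]] <- m
      log[[length(log) + 1]] <- list(class = cl, contributors = contrib)
    }
  }
  if (guard_violations > 0) {
    rlang::inform(paste0(
      guard_violations, " artificial epoch(s) fell outside the 1.5x ",
      "contributor variance envelope (kept; logged)."
    ))
  }
  if (length(new_data) == 0) return(epochs)
  epoch_set(
    c(epochs$data, new_data),
    epochs$channel_names, epochs$sampling_rate,
    dplyr::bind_rows(epochs$meta, dplyr::bind_rows(new_meta)),
    c(epochs$metadata,
      list(augmentation_log = log, augmentation_ratio = ratio,
           augmentation_mode = mode))
  )
}
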