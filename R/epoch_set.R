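#' Labelled collection of multichannel EEG epochs
#'
#' The core signal container: an ordered list of channels-x-samples
#' matrices (microvolts), one per trial, sharing channel names and a
#' sampling rate, plus a per-trial metadata tibble (`subject`, `trial`,
#' label columns, and an `augmented` provenance flag). Samples are
#' 0-based when addressed by window spans; spans are half-open
#' `[start, end)`.
#'
#' @param data List of numeric matrices, each channels x samples.
#' @param channel_names Character vector of unique channel names.
#' @param sampling_rate Sampling rate in Hz.
#' @param meta Tibble with one row per trial; columns `subject` and
#'   `trial` required. Label columns depend on the labelling scheme:
#'   `valence`/`arousal` (1-9) or `class` (factor). An `augmented`
#'   logical column is added if missing.
#' @param metadata Optional named list of free-form set-level metadata.
#'
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, channel_names, sampling_rate, meta,
                      metadata = list()) {
  stopifnot(is.list(data), length(data) >= 1)
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  n_ch <- nrow(data[[1]])
  if (length(channel_names) != n_ch || anyDuplicated(channel_names) > 0) {
    abort("channel_names must be unique and match the channel count.",
          class = "emoselect_epochs_error")
  }
  if (!all(vapply(data, nrow, 0L) == n_ch)) {
    abort("All trials must share the same channel count.",
          class = "emoselect_epochs_error")
  }
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != length(data) ||
      !all(c("subject", "trial") %in% names(meta))) {
    abort("meta needs one row per trial with columns subject and trial.",
          class = "emoselect_epochs_error")
  }
  if (!"augmented" %in% names(meta)) meta$augmented <- FALSE
  structure(
    list(
      data = data,
      channel_names = as.character(channel_names),
      sampling_rate = sampling_rate,
      meta = meta,
      metadata = metadata
    ),
    class = "epoch_set"
  )
}

#' @exportS3Method base::print
print.epoch_set <- function(x, ...) {
  ns <- unique(vapply(x$data, ncol, 0L))
  cat("<epoch_set> ", n_trials(x), " trials, ",
      length(x$channel_names), " channels @ ", x$sampling_rate, " Hz, ",
      paste(ns, collapse = "/"), " samples/trial\n", sep = "")
  cat("  subjects: ", length(unique(x$meta$subject)),
      "; augmented trials: ", sum(x$meta$augmented), "\n", sep = "")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) length(x$data)

#' Subset an epoch set by trial
#' @param x An `epoch_set`.
#' @param i Trial indices (integer or logical).
#' @param ... Unused.
#' @return An `epoch_set` with the selected trials.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  idx <- seq_len(n_trials(x))[i]
  epoch_set(x$data[idx], x$channel_names, x$sampling_rate,
            x$meta[idx, , drop = FALSE], x$metadata)
}

#' @describeIn epoch_set Per-trial metadata as a tibble.
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @export
tidy.epoch_set <- function(x, ...) x$meta

#' @describeIn epoch_set One-row summary (trials, channels, rate, samples).
#' @export
glance.epoch_set <- function(x, ...) {
  tibble::tibble(
    n_trials = n_trials(x),
    n_subjects = length(unique(x$meta$subject)),
    n_channels = length(x$channel_names),
    sampling_rate = x$sampling_rate,
    n_samples = ncol(x$data[[1]]),
    n_augmented = sum(x$meta$augmented)
  )
}

#' Restrict an epoch set to a subset of channels
#'
#' @param epochs An `epoch_set`.
#' @param channels Character vector of channel names (order preserved as
#'   given) or integer indices.
#' @return An `epoch_set` containing only the requested channels.
#' @export
select_epoch_channels <- function(epochs, channels) {
  if (is.character(channels)) {
    idx <- match(channels, epochs$channel_names)
    if (anyNA(idx)) {
      abort(paste0("Unknown channels: ",
                   paste(channels[is.na(idx)], collapse = ", ")),
            class = "emoselect_epochs_error")
    }
  } else {
    idx <- as.integer(channels)
  }
  epoch_set(
    lapply(epochs$data, function(m) m[idx, , drop = FALSE]),
    epochs$channel_names[idx], epochs$sampling_rate, epochs$meta,
    epochs$metadata
  )
}

#' Per-trial class labels for a classification task
#'
#' Maps the stored label columns to the factor used by the classifier:
#' `binary_valence` / `binary_arousal` binarize the 1-9 rating at 5
#' (see [binarize_sam()]), `three_class` uses the categorical `class`
#' column.
#'
#' @param epochs An `epoch_set`.
#' @param task `"binary_valence"`, `"binary_arousal"` or `"three_class"`.
#' @return Factor of length `n_trials(epochs)`.
#' @export
epoch_labels <- function(epochs,
                         task = c("binary_valence", "binary_arousal",
                                  "three_class")) {
  task <- match.arg(task)
  meta <- epochs$meta
  if (task == "three_class") {
    if (!"class" %in% names(meta)) {
      abort("three_class task requires a 'class' label column.",
            class = "emoselect_label_error")
    }
    return(factor(meta$class))
  }
  col <- if (task == "binary_valence") "valence" else "arousal"
  if (!col %in% names(meta)) {
    abort(paste0(task, " requires a '", col, "' rating column."),
          class = "emoselect_label_error")
  }
  binarize_sam(meta[[col]])
}
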