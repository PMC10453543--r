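#' Write an epoch set as a plain-text fixture directory
#'
#' Layout: `epochs/<subject>_<trial>.csv` (samples as rows, one column
#' per channel, header row of channel names), `labels.tsv` (one row per
#' trial: subject, trial, label columns, augmented flag) and
#' `profile.yaml` (sampling rate and geometry).
#'
#' @param epochs An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @param format `"csv_dir"` (plain text) or `"edf"` (one EDF file per
#'   trial; 16-bit quantized, see [write_edf()]).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir, format = c("csv_dir", "edf")) {
  format <- match.arg(format)
  ep_dir <- file.path(dir, "epochs")
  dir.create(ep_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- epochs$meta
  for (i in seq_len(n_trials(epochs))) {
    stem <- sprintf("%03d_%03d", meta$subject[i], meta$trial[i])
    if (format == "csv_dir") {
      # %.17g guarantees bit-exact double round-trips through text
      m <- matrix(sprintf("%.17g", t(epochs$data[[i]])),
                  ncol = length(epochs$channel_names))
      colnames(m) <- epochs$channel_names
      utils::write.table(m, file.path(ep_dir, paste0(stem, ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
    } else {
      write_edf(epochs$data[[i]], file.path(ep_dir, paste0(stem, ".edf")),
                epochs$sampling_rate, epochs$channel_names)
    }
  }
  utils::write.table(meta, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(sampling_rate = epochs$sampling_rate,
         n_channels = length(epochs$channel_names),
         channel_names = epochs$channel_names,
         format = format,
         metadata = lapply(epochs$metadata, function(v) {
           if (length(v) == 0) NULL else v
         })),
    file.path(dir, "profile.yaml")
  )
  invisible(dir)
}

#' Read an epoch set from a fixture directory or EDF directory
#'
#' Counterpart of [write_epochs()]: reads `epochs/*.csv` or
#' `epochs/*.edf` together with the sidecar `labels.tsv` (required) and
#' `profile.yaml` (optional; used to check the sampling rate). All
#' trials must agree on channel set and sampling rate; a mismatch is an
#' error, not a warning.
#'
#' @param path Fixture directory.
#' @param format `"csv_dir"` or `"edf"`.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path, format = c("csv_dir", "edf")) {
  format <- match.arg(format)
  lab_path <- file.path(path, "labels.tsv")
  if (!file.exists(lab_path)) {
    abort("labels.tsv sidecar is missing.", class = "emoselect_io_error")
  }
  meta <- tibble::as_tibble(utils::read.delim(lab_path, sep = "\t"))
  if ("class" %in% names(meta)) meta$class <- factor(meta$class)
  ext <- if (format == "csv_dir") "csv" else "edf"
  ep_dir <- file.path(path, "epochs")
  files <- file.path(
    ep_dir, sprintf("%03d_%03d.%s", meta$subject, meta$trial, ext)
  )
  missing <- !file.exists(files)
  if (any(missing)) {
    abort(paste0("Missing epoch files: ",
                 paste(basename(files[missing]), collapse = ", ")),
          class = "emoselect_io_error")
  }
  prof <- NULL
  prof_path <- file.path(path, "profile.yaml")
  if (file.exists(prof_path)) prof <- yaml::read_yaml(prof_path)

  channel_names <- NULL
  rate <- prof$sampling_rate %||% NULL
  data <- vector("list", length(files))
  for (i in seq_along(files)) {
    if (format == "csv_dir") {
      m <- utils::read.csv(files[i], check.names = FALSE)
      cn <- colnames(m)
      x <- t(as.matrix(m))
      r <- rate
    } else {
      edf <- read_edf(files[i])
      cn <- edf$channel_names
      x <- edf$data
      r <- edf$sampling_rate
    }
    if (is.null(channel_names)) channel_names <- cn
    if (!identical(cn, channel_names)) {
      abort("Inconsistent channel sets across epoch files.",
            class = "emoselect_io_error")
    }
    if (is.null(rate)) rate <- r
    if (!is.null(r) && !isTRUE(all.equal(r, rate))) {
      abort("Sampling-rate mismatch across epoch files.",
            class = "emoselect_io_error")
    }
    data[[i]] <- x
  }
  if (is.null(rate)) {
    abort("Sampling rate unavailable (no profile.yaml and no EDF header).",
          class = "emoselect_io_error")
  }
  epoch_set(data, channel_names, rate, meta,
            metadata = prof$metadata %||% list())
}
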