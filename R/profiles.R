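#' Built-in synthetic dataset profiles
#'
#' Recording geometries mirroring three widely used affective-EEG corpora:
#' a DEAP-like layout (32 subjects, 40 trials, 32 channels, 128 Hz, 60-s
#' music-video trials, 1-9 valence/arousal ratings), a MAHNOB-HCI-like
#' layout (27 subjects, 20 trials, 32 channels, 256 Hz) and a SEED-like
#' layout (15 subjects, 15 trials, 62 channels, 128 Hz, 240-s film-clip
#' trials, three categorical emotion classes). MAHNOB-HCI clips vary from
#' roughly 34 s to 117 s in the original recordings; the profile defaults
#' to a fixed 60 s (15,360 samples at 256 Hz) and the duration can be
#' overridden.
#'
#' @param name One of `"deap_like"`, `"mahnob_like"`, `"seed_like"`.
#' @param trial_duration Optional duration override in seconds.
#'
#' @return A `dataset_profile` object: a list with fields `name`,
#'   `n_subjects`, `n_trials_per_subject`, `n_channels`, `sampling_rate`,
#'   `trial_duration`, `label_scheme` and `channel_names`.
#' @examples
#' builtin_profile("deap_like")
#' @export
builtin_profile <- function(name, trial_duration = NULL) {
  known <- list(
    deap_like = dataset_profile(
      name = "deap_like", n_subjects = 32, n_trials_per_subject = 40,
      n_channels = 32, sampling_rate = 128, trial_duration = 60,
      label_scheme = "valence_arousal_1to9",
      channel_names = biosemi32_names()
    ),
    mahnob_like = dataset_profile(
      name = "mahnob_like", n_subjects = 27, n_trials_per_subject = 20,
      n_channels = 32, sampling_rate = 256, trial_duration = 60,
      label_scheme = "valence_arousal_1to9",
      channel_names = biosemi32_names()
    ),
    seed_like = dataset_profile(
      name = "seed_like", n_subjects = 15, n_trials_per_subject = 15,
      n_channels = 62, sampling_rate = 128, trial_duration = 240,
      label_scheme = "categorical_3class",
      channel_names = seed62_names()
    )
  )
  if (!name %in% names(known)) {
    abort(paste0(
      "Unknown profile '", name, "'. Built-in profiles: ",
      paste(names(known), collapse = ", "), "."
    ), class = "emoselect_profile_error")
  }
  prof <- known[[name]]
  if (!is.null(trial_duration)) {
    prof <- dataset_profile(
      name = prof$name, n_subjects = prof$n_subjects,
      n_trials_per_subject = prof$n_trials_per_subject,
      n_channels = prof$n_channels, sampling_rate = prof$sampling_rate,
      trial_duration = trial_duration, label_scheme = prof$label_scheme,
      channel_names = prof$channel_names
    )
  }
  prof
}

#' Construct a dataset profile
#'
#' @param name Profile name.
#' @param n_subjects,n_trials_per_subject,n_channels Positive counts.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_duration Trial duration in seconds;
#'   `trial_duration * sampling_rate` must be an integer.
#' @param label_scheme `"valence_arousal_1to9"` or `"categorical_3class"`.
#' @param channel_names Optional character vector of channel names
#'   (10-20 nomenclature); autogenerated `ch01..` names otherwise.
#' @return A `dataset_profile` object.
#' @export
dataset_profile <- function(name, n_subjects, n_trials_per_subject,
                            n_channels, sampling_rate, trial_duration,
                            label_scheme = c("valence_arousal_1to9",
                                             "categorical_3class"),
                            channel_names = NULL) {
  label_scheme <- match.arg(label_scheme)
  stopifnot(
    is_count(n_subjects), is_count(n_trials_per_subject),
    is_count(n_channels),
    is.numeric(sampling_rate), sampling_rate > 0,
    is.numeric(trial_duration), trial_duration > 0
  )
  n_samples <- trial_duration * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("trial_duration * sampling_rate must be an integer sample count.",
          class = "emoselect_profile_error")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels ||
      anyDuplicated(channel_names) > 0) {
    abort("channel_names must be unique and match n_channels.",
          class = "emoselect_profile_error")
  }
  structure(
    list(
      name = name, n_subjects = n_subjects,
      n_trials_per_subject = n_trials_per_subject,
      n_channels = n_channels, sampling_rate = sampling_rate,
      trial_duration = trial_duration,
      n_samples = as.integer(round(n_samples)),
      label_scheme = label_scheme, channel_names = channel_names
    ),
    class = "dataset_profile"
  )
}

#' @exportS3Method base::print
print.dataset_profile <- function(x, ...) {
  cat("<dataset_profile> ", x$name, "\n", sep = "")
  cat("  ", x$n_subjects, " subjects x ", x$n_trials_per_subject,
      " trials, ", x$n_channels, " channels @ ", x$sampling_rate,
      " Hz, ", x$trial_duration, " s (", x$n_samples, " samples), labels: ",
      x$label_scheme, "\n", sep = "")
  invisible(x)
}

# 32-channel Biosemi layout used by the DEAP and MAHNOB-HCI recordings.
biosemi32_names <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

# 62-channel extended 10-20 layout as used by SEED-style caps.
seed62_names <- function() {
  c("Fp1", "Fpz", "Fp2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "CB1", "O1", "Oz", "O2", "CB2")
}

#' Binarize a 1-9 self-assessment (SAM) rating
#'
#' Affective ratings on the 1-9 self-assessment manikin scale are split
#' into `"low"` (rating <= 5) and `"high"` (rating > 5), applied
#' independently to the valence and arousal axes.
#'
#' @param rating Numeric vector of ratings in `[1, 9]`.
#' @return Factor with levels `c("low", "high")`.
#' @examples
#' binarize_sam(c(1, 5, 6, 9))
#' @export
binarize_sam <- function(rating) {
  if (!is.numeric(rating) || any(!is.finite(rating)) ||
      any(rating < 1 | rating > 9)) {
    abort("Ratings must be numeric values in [1, 9].",
          class = "emoselect_label_error")
  }
  factor(ifelse(rating > 5, "high", "low"), levels = c("low", "high"))
}
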