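#' Canonical synthetic benchmarks
#'
#' Fixed synthetic study designs used by the package's own validation
#' suite, so tests, examples and the acceptance script all exercise the
#' same conditions:
#'
#' * `"planted"` - channel/window recovery design: 32-channel DEAP-like
#'   geometry at 128 Hz, 8 subjects x 20 trials of 50 s, with 10
#'   informative channels and 20 informative 2-s windows (ordinals
#'   2-21) at strong class contrast. Used to check that the
#'   relevance-score top-10 channels and the DMIM top-20 windows
#'   recover the planted structure.
#' * `"learnability"` - compact end-to-end design: 8 subjects x 20
#'   trials, 8 channels, 128 Hz, 12-s trials, 1-s windows, 2
#'   informative channels (C3, C4) and 3 informative windows at strong
#'   contrast; the pipeline keeps 2 channels and 2 windows, giving the
#'   classifier a 512-sample input.
#' * `"augmentation"` - the learnability geometry shrunk to 4 subjects
#'   x 12 trials, for augmentation-trend comparisons.
#' * `"null"` - the augmentation geometry with no informative
#'   channels/windows (pure 1/f noise): end-to-end accuracy must sit
#'   at chance.
#'
#' @param kind Benchmark name (see above).
#' @param seed Integer seed passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
benchmark_spec <- function(kind = c("planted", "learnability",
                                    "augmentation", "null"),
                           seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "planted") {
    prof <- dataset_profile(
      "planted_recovery", n_subjects = 8, n_trials_per_subject = 20,
      n_channels = 32, sampling_rate = 128, trial_duration = 50,
      label_scheme = "valence_arousal_1to9",
      channel_names = biosemi32_names()
    )
    return(synthetic_spec(
      prof,
      informative_channels = planted_channels(),
      informative_windows = 2:21,
      window_seconds = 2, seed = seed
    ))
  }
  small_names <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  prof <- dataset_profile(
    paste0(kind, "_benchmark"),
    n_subjects = if (kind == "learnability") 8 else 4,
    n_trials_per_subject = if (kind == "learnability") 20 else 12,
    n_channels = 8, sampling_rate = 128, trial_duration = 12,
    label_scheme = "valence_arousal_1to9",
    channel_names = small_names
  )
  if (kind == "null") {
    return(synthetic_spec(prof, integer(), integer(),
                          window_seconds = 1, seed = seed))
  }
  # sustained (non-intermittent) bursts: these benchmarks probe the
  # classifier, not selection-stage complementarity
  synthetic_spec(
    prof,
    informative_channels = c("C3", "C4"),
    informative_windows = c(3, 6, 9),
    window_seconds = 1, burst_prob = 1, seed = seed
  )
}

# The 10 planted channels of the recovery benchmark: a frontal /
# central / parietal set typical of emotion studies.
planted_channels <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "C3", "C4", "P3", "P4")
}

#' Pipeline configuration matched to a benchmark
#'
#' @param kind Benchmark name, see [benchmark_spec()].
#' @param augment_ratio Augmentation ratio (training folds only).
#' @param epochs Training epochs for the compact benchmarks.
#' @param seed Run seed.
#' @return A [pipeline_config()].
#' @export
benchmark_pipeline_config <- function(kind = c("learnability",
                                               "augmentation", "null"),
                                      augment_ratio = 0, epochs = 12,
                                      seed = 1L) {
  kind <- match.arg(kind)
  pipeline_config(
    task = "binary_valence", n_channels = 2, window_seconds = 1,
    top_windows = 2, augment_ratio = augment_ratio,
    epochs_override = epochs, seed = seed
  )
}
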