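#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's trials form the test set, all
#' other subjects' trials the training set. Folds partition the data;
#' no subject ever appears on both sides of a fold.
#'
#' @param epochs An [epoch_set()].
#' @return Tibble with columns `fold`, `subject`, and list-columns
#'   `train` / `test` of trial indices.
#' @export
loso_splits <- function(epochs) {
  subjects <- unique(epochs$meta$subject)
  if (length(subjects) < 2) {
    abort("Leave-one-subject-out needs at least 2 subjects.",
          class = "emoselect_eval_error")
  }
  tibble::tibble(
    fold = seq_along(subjects),
    subject = subjects,
    train = lapply(subjects, function(s) {
      which(epochs$meta$subject != s)
    }),
    test = lapply(subjects, function(s) {
      which(epochs$meta$subject == s)
    })
  )
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()]: classification task, channel
#' selection (bins, number of channels kept per fold, optional score
#' threshold), windowing and DMIM top-k, augmentation ratio and mode,
#' and the CNN configuration.
#'
#' @param task Classification task, see [epoch_labels()].
#' @param n_channels Channels kept per fold (rank-based on the
#'   relevance score, so the classifier input shape is constant
#'   across folds). Set `channel_threshold` to additionally require a
#'   minimum score.
#' @param channel_threshold Optional minimum relevance score.
#' @param n_bins Amplitude bins for channel scoring.
#' @param window_seconds Window length for feature extraction.
#' @param top_windows DMIM features kept.
#' @param augment_ratio Graph-EMD augmentation ratio for training
#'   folds (0 = off). Test folds never receive artificial epochs.
#' @param augment_mode `"temporal"` or `"product"`.
#' @param model A [model_config()].
#' @param epochs_override Optional training-epoch override.
#' @param seed Integer seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(task = "binary_valence",
                            n_channels = 10,
                            channel_threshold = NULL,
                            n_bins = 32,
                            window_seconds = 2,
                            top_windows = 20,
                            augment_ratio = 0,
                            augment_mode = "temporal",
                            model = model_config(),
                            epochs_override = NULL,
                            seed = 1L) {
  structure(
    list(task = task, n_channels = n_channels,
         channel_threshold = channel_threshold, n_bins = n_bins,
         window_seconds = window_seconds, top_windows = top_windows,
         augment_ratio = augment_ratio, augment_mode = augment_mode,
         model = model, epochs_override = epochs_override,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full selection-augmentation-classification pipeline
#'
#' For every leave-one-subject-out fold: score channels on the
#' training trials and keep the top `n_channels`; extract per-window
#' differential-entropy features and keep the `top_windows` best DMIM
#' windows; map the selected spans back to raw samples; optionally
#' augment the training epochs class-conditionally by graph-EMD
#' mixing (artificial epochs never enter test folds); standardize per
#' channel on training statistics; train the 1D-CNN; evaluate on the
#' held-out subject. The per-fold p-score compares the held-out
#' subject's per-trial mean DE over the selected windows with the
#' mean over all windows.
#'
#' @param epochs An [epoch_set()].
#' @param config A [pipeline_config()].
#' @return An `eval_report`: list with `per_fold` (one metric row per
#'   subject), `summary` (mean metrics, pooled kappa, selection-cost
#'   index), `config`. `tidy()` and `glance()` return the two tibbles.
#' @export
run_pipeline <- function(epochs, config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(config, "pipeline_config"))
  labels_all <- epoch_labels(epochs, config$task)
  folds <- loso_splits(epochs)
  fold_rows <- vector("list", nrow(folds))
  pooled_truth <- list()
  pooled_pred <- list()
  for (fi in seq_len(nrow(folds))) {
    tr_idx <- folds$train[[fi]]
    te_idx <- folds$test[[fi]]
    tr <- epochs[tr_idx]
    te <- epochs[te_idx]
    y_tr <- droplevels(labels_all[tr_idx])
    y_te <- factor(labels_all[te_idx], levels = levels(y_tr))

    # channel selection on training folds only
    tbl <- score_channels(tr, labels = y_tr, n_bins = config$n_bins)
    sel <- select_channels(tbl,
                           threshold = config$channel_threshold %||% 0)
    sel <- utils::head(sel, config$n_channels)
    if (nrow(sel) == 0) {
      abort("Channel selection returned no channels.",
            class = "emoselect_eval_error")
    }
    tr_ch <- select_epoch_channels(tr, sel$channel)
    te_ch <- select_epoch_channels(te, sel$channel)

    # DMIM window selection on training folds only
    feats_tr <- window_features(tr_ch, config$window_seconds)
    ranking <- dmim_rank(feats_tr, y_tr, k = config$top_windows)
    spans <- select_top_windows(ranking, config$top_windows)
    tr_red <- map_to_raw(tr_ch, spans)
    te_red <- map_to_raw(te_ch, spans)

    if (config$augment_ratio > 0) {
      tr_red <- augment_dataset(
        tr_red, ratio = config$augment_ratio, labels = y_tr,
        mode = config$augment_mode,
        seed = child_seed(config$seed, 1000 + fi)
      )
      y_tr <- droplevels(epoch_labels(tr_red, config$task))
    }

    # per-channel standardization with training statistics
    X_tr <- epochs_to_input(tr_red)
    X_te <- epochs_to_input(te_red)
    n_ch <- length(tr_red$channel_names)
    seg <- rep(seq_len(n_ch), each = nrow(X_tr) / n_ch)
    mu <- as.vector(tapply(rowMeans(X_tr), seg, mean))[seg]
    sdv <- vapply(split(seq_len(nrow(X_tr)), seg), function(ix) {
      s <- sd(as.vector(X_tr[ix, ]))
      if (s == 0) 1 else s
    }, 0)[seg]
    X_tr <- (X_tr - mu) / sdv
    X_te <- (X_te - mu) / sdv

    mdl <- build_model(config$model, n_in = nrow(X_tr),
                       n_classes = nlevels(y_tr),
                       seed = child_seed(config$seed, fi))
    mdl <- train(mdl, X_tr, y_tr, epochs = config$epochs_override,
                 seed = child_seed(config$seed, fi))
    pred <- predict(mdl, X_te)
    cm <- confusion_matrix(y_te, pred)
    met <- confusion_metrics(cm)

    # per-subject p-score on the held-out trials
    feats_te <- window_features(te_ch, config$window_seconds)
    sel_w <- unique(spans$window)
    by_trial <- feats_te |>
      dplyr::group_by(.data$trial) |>
      dplyr::summarise(
        selected = mean(.data$de[.data$window %in% sel_w]),
        original = mean(.data$de), .groups = "drop"
      )
    p <- if (nrow(by_trial) >= 2) {
      p_score(by_trial$selected, by_trial$original)
    } else {
      NA_real_
    }
    fold_rows[[fi]] <- dplyr::bind_cols(
      tibble::tibble(fold = fi, subject = folds$subject[fi],
                     n_test = length(te_idx)),
      met, tibble::tibble(p_score = p)
    )
    pooled_truth[[fi]] <- as.character(y_te)
    pooled_pred[[fi]] <- as.character(pred)
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  truth <- factor(unlist(pooled_truth), levels = levels(labels_all))
  pred <- factor(unlist(pooled_pred), levels = levels(labels_all))
  pooled_cm <- confusion_matrix(truth, pred)
  n_all_windows <- nrow(segment_windows(epochs, config$window_seconds))
  f_v <- min(max(config$top_windows / n_all_windows, 1e-6), 1 - 1e-6)
  class_prop <- as.numeric(table(labels_all) / length(labels_all))
  summary <- tibble::tibble(
    accuracy = mean(per_fold$accuracy),
    precision = mean(per_fold$precision),
    specificity = mean(per_fold$specificity),
    recall = mean(per_fold$recall),
    f1 = mean(per_fold$f1),
    p_score = mean(per_fold$p_score, na.rm = TRUE),
    kappa = kappa(pooled_cm),
    selection_cost = selection_cost(
      f_v, config$n_channels * config$top_windows *
        round(config$window_seconds * epochs$sampling_rate),
      class_prop, nlevels(labels_all)
    )
  )
  structure(
    list(per_fold = per_fold, summary = summary,
         confusion = pooled_cm, config = config),
    class = "eval_report"
  )
}

# Flatten a reduced epoch set to the CNN input matrix: each trial's
# channels are concatenated time-major, giving an n_in x n_trials
# matrix.
epochs_to_input <- function(epochs) {
  vapply(epochs$data, function(m) as.vector(t(m)),
         numeric(nrow(epochs$data[[1]]) * ncol(epochs$data[[1]])))
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x$per_fold), "LOSO folds\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn run_pipeline Per-fold metric rows.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' @describeIn run_pipeline One-row summary (means, kappa, cost index).
#' @export
glance.eval_report <- function(x, ...) x$summary

#' Write an evaluation report as TSV files
#'
#' `report.tsv` holds the per-fold metric rows, `summary.tsv` the
#' one-row mean/kappa summary.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_fold, file.path(dir, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
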