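#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline labs facet_wrap theme_minimal coord_fixed
NULL

#' @export
ggplot2::autoplot

#' Plot per-channel relevance scores
#'
#' Bar chart of the per-class channel scores with the selection
#' threshold overlaid.
#'
#' @param object A `channel_score_table` from [score_channels()].
#' @param threshold Optional threshold line (default 1.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_score_table <- function(object, threshold = 1.5, ...) {
  ggplot(object, aes(x = stats::reorder(.data$channel,
                                        -.data$max_score),
                     y = .data$score, fill = .data$class)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = threshold, linetype = 2) +
    labs(x = "channel", y = "relevance score (bits)",
         fill = "class") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a DMIM selection trace
#'
#' Objective decomposition (relevance, redundancy, conditional
#' redundancy, total score) along the greedy selection path.
#'
#' @param object A `dmim_ranking` from [dmim_rank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmim_ranking <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::all_of(c("step", "relevance", "redundancy",
                                  "cond_redundancy", "score"))) |>
    tidyr::pivot_longer(-"step", names_to = "term",
                        values_to = "value")
  ggplot(long, aes(x = .data$step, y = .data$value,
                   colour = .data$term)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "selection step", y = "nats", colour = NULL) +
    theme_minimal()
}

#' Plot per-fold evaluation metrics
#'
#' @param object An `eval_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- object$per_fold |>
    dplyr::select(dplyr::all_of(c("subject", "accuracy", "precision",
                                  "specificity", "recall", "f1"))) |>
    tidyr::pivot_longer(-"subject", names_to = "metric",
                        values_to = "value")
  ggplot(long, aes(x = factor(.data$subject), y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric) +
    labs(x = "held-out subject", y = NULL) +
    theme_minimal()
}

#' Plot a training history
#'
#' @param object A fitted `cnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "series",
                              values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a montage
#'
#' Top-down scalp projection (x right, y nasion-ward) of resolved
#' electrode positions.
#'
#' @param object A `montage` from [standard_1020_montage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.montage <- function(object, ...) {
  res <- object[object$resolved, ]
  ggplot(res, aes(x = .data$x, y = .data$y,
                  label = .data$channel)) +
    geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
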