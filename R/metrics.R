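#' Confusion matrix from predicted and true labels
#'
#' @param truth,estimate Factors (coerced) over the same levels.
#' @return A K x K integer table, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, estimate) {
  truth <- as.factor(truth)
  estimate <- factor(estimate, levels = levels(truth))
  table(truth = truth, estimate = estimate)
}

#' Classification metric bundle from a confusion matrix
#'
#' Binary case (positive class = second level): accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, `F1 = 2PR/(P+R)`. K-class tables are
#' macro-averaged one-vs-rest. Undefined ratios (zero denominators)
#' are reported as 0 and flagged via the `degenerate` column.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return One-row tibble: `accuracy`, `precision`, `specificity`,
#'   `recall`, `f1`, `degenerate`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) {
    abort("Counts must be non-negative.",
          class = "emoselect_metric_error")
  }
  total <- sum(cm)
  if (total == 0) {
    abort("Empty confusion matrix.", class = "emoselect_metric_error")
  }
  K <- nrow(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  one_vs_rest <- function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    c(precision = safe_div(tp, tp + fp),
      recall = safe_div(tp, tp + fn),
      specificity = safe_div(tn, tn + fp),
      degenerate = (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0))
  }
  if (K == 2) {
    m <- one_vs_rest(2) # positive class = second level
  } else {
    per_class <- vapply(seq_len(K), one_vs_rest, numeric(4))
    m <- c(rowMeans(per_class[1:3, , drop = FALSE]),
           degenerate = any(per_class[4, ] > 0))
  }
  prec <- unname(m["precision"])
  rec <- unname(m["recall"])
  tibble::tibble(
    accuracy = sum(diag(cm)) / total,
    precision = prec,
    specificity = unname(m["specificity"]),
    recall = rec,
    f1 = safe_div(2 * prec * rec, prec + rec),
    degenerate = as.logical(m["degenerate"])
  )
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the marginals. A table with `p_e = 1` returns
#' 0 with a warning (agreement cannot be distinguished from chance).
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Scalar kappa in `[-1, 1]`.
#' @export
kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) {
    abort("Empty confusion matrix.", class = "emoselect_metric_error")
  }
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) {
    warn("Expected agreement is 1; kappa undefined, returning 0.")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Paired t-test p-score between selected and original feature vectors
#'
#' Two-sided one-sample t-test on the paired differences between a
#' per-trial summary of the selected features (e.g. mean differential
#' entropy over the selected windows) and the same summary over all
#' windows. All-zero differences (selected identical to original)
#' return p = 1 with a warning, the defined limit of the test.
#'
#' @param selected,original Numeric vectors of equal length (one
#'   summary value per trial).
#' @return p-value in `[0, 1]`.
#' @export
p_score <- function(selected, original) {
  stopifnot(length(selected) == length(original))
  if (length(selected) < 2) {
    abort("Need at least 2 pairs for the t-test.",
          class = "emoselect_metric_error")
  }
  d <- selected - original
  if (all(abs(d - d[1]) < 1e-14) && abs(d[1]) < 1e-14) {
    warn("Selected equals original; p-score is 1 by definition.")
    return(1)
  }
  tryCatch(
    t.test(d)$p.value,
    error = function(e) {
      # numerically constant differences: the t statistic degenerates
      if (abs(mean(d)) > 1e-12) 0 else 1
    }
  )
}

#' Selection-cost index of a feature-selection configuration
#'
#' Dimensionless index
#' `CT = (1/F_T) * sum_ci [ C_P ln(f_v) + (1 - C_P) ln(1 - f_v) ]`
#' summed over the `C` classes, where `f_v` is the selected feature
#' value (a fraction in (0,1)), `F_T` the training-feature count and
#' `C_P` the class-specific feature proportion. Always non-positive
#' for valid inputs; closer to 0 means a cheaper configuration. This
#' is an index, not a wall-clock measurement.
#'
#' @param f_v Selected feature value, strictly inside (0, 1).
#' @param F_T Training feature count (> 0).
#' @param C_P Class-specific proportion(s) in `[0, 1]`; scalar or one
#'   value per class.
#' @param n_classes Number of classes `C`.
#' @return Scalar index `CT` (<= 0).
#' @examples
#' selection_cost(0.5, 100, 0.3, 2) # = 2 * log(0.5) / 100
#' @export
selection_cost <- function(f_v, F_T, C_P, n_classes) {
  if (!(f_v > 0 && f_v < 1)) {
    abort("f_v must lie strictly inside (0, 1).",
          class = "emoselect_metric_error")
  }
  stopifnot(F_T > 0, n_classes >= 1, all(C_P >= 0), all(C_P <= 1))
  C_P <- rep_len(C_P, n_classes)
  sum(C_P * log(f_v) + (1 - C_P) * log(1 - f_v)) / F_T
}
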