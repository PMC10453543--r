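# Shared fixture builders: all programmatic, no files.

toy_profile <- function(n_subjects = 2, n_trials = 4, n_channels = 4,
                        rate = 128, duration = 4,
                        scheme = "valence_arousal_1to9") {
  dataset_profile("toy", n_subjects, n_trials, n_channels, rate,
                  duration, label_scheme = scheme,
                  channel_names = c("F3", "F4", "C3", "C4",
                                    "P3", "P4", "O1", "O2")[
                                      seq_len(n_channels)])
}

toy_epochs <- function(n_subjects = 2, n_trials = 4, n_channels = 4,
                       rate = 128, duration = 4, seed = 1, ...) {
  generate_epoch_set(synthetic_spec(
    toy_profile(n_subjects, n_trials, n_channels, rate, duration),
    seed = seed, ...
  ))
}

# Independent brute-force enumeration of the channel relevance score:
# literal per-trial loop over the definition, no shared code with the
# package implementation.
brute_channel_score <- function(symbol_list, labels, class_c) {
  x_C <- sort(unique(unlist(symbol_list[labels == class_c])))
  terms <- vapply(symbol_list, function(sym) {
    ratio <- sum(sym %in% x_C) / length(sym)
    if (ratio == 0) ratio <- 1 / (length(sym) + 1)
    log2(ratio)
  }, 0)
  -mean(terms)
}

# Fake discretized container from explicit per-trial symbol vectors
# (single channel).
disc_from_symbols <- function(symbol_list, n_bins) {
  n_tr <- length(symbol_list)
  counts <- array(0L, c(n_bins, n_tr, 1))
  for (i in seq_len(n_tr)) {
    counts[, i, 1] <- tabulate(symbol_list[[i]], nbins = n_bins)
  }
  structure(
    list(symbols = NULL, bin_edges = NULL, n_bins = n_bins,
         counts = counts, constant_channels = FALSE,
         channel_names = "ch"),
    class = "discretized_epochs"
  )
}

# Brute-force discrete MI in nats from two vectors.
brute_mi <- function(a, b) {
  ta <- table(a) / length(a)
  tb <- table(b) / length(b)
  tj <- table(a, b) / length(a)
  s <- 0
  for (i in rownames(tj)) for (j in colnames(tj)) {
    p <- tj[i, j]
    if (p > 0) s <- s + p * log(p / (ta[[i]] * tb[[j]]))
  }
  unname(s)
}

brute_cmi <- function(a, b, cls) {
  s <- 0
  for (c_ in unique(cls)) {
    idx <- cls == c_
    if (sum(idx) >= 2) s <- s + mean(idx) * brute_mi(a[idx], b[idx])
  }
  s
}
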