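test_that("signal graphs have the promised structure", {
  g <- build_signal_graph(5, "temporal")
  expect_equal(sum(g$A) / 2, 4) # path on 5 vertices has 4 edges
  deg <- Matrix::rowSums(g$A > 0)
  expect_true(all(deg <= 2))
  expect_equal(Matrix::rowSums(g$L), rep(0, 5)) # Laplacian row sums
  # Laplacian annihilates constants
  expect_equal(as.vector(g$L %*% rep(1, 5)), rep(0, 5))

  mont <- standard_1020_montage(c("F3", "F4", "C3", "C4", "P3",
                                  "P4", "O1", "O2", "Fz", "Pz"))
  gp <- build_signal_graph(32, "product", montage = mont, knn = 3)
  expect_equal(nrow(gp$A), 10 * 32) # product cardinality
  expect_true(Matrix::isSymmetric(gp$A))
  expect_equal(max(abs(gp$L %*% rep(1, 320))), 0)

  bad <- suppressWarnings(standard_1020_montage(c("F3", "XX1")))
  expect_error(build_signal_graph(8, "product", montage = bad),
               class = "emoselect_graph_error")
})

test_that("decomposition reconstructs and respects the IMF cap", {
  g <- build_signal_graph(512, "temporal")
  # constant signal: no extrema, no IMFs
  dc <- decompose(matrix(2, 1, 512), g)
  expect_equal(dc$n_imfs, 0)
  expect_equal(dc$residual, matrix(2, 1, 512))

  set.seed(4)
  for (s in 1:5) {
    x <- matrix(rnorm(2 * 512), 2)
    d <- decompose(x, g, max_imfs = 5)
    expect_lte(d$n_imfs, 5)
    recon <- Reduce(`+`, d$imfs, accumulate = FALSE) + d$residual
    expect_lt(sqrt(sum((recon - x)^2) / sum(x^2)), 1e-8)
  }

  # fast + slow separation in temporal mode (classical-EMD behaviour)
  tt <- (1:512) / 128
  x <- matrix(sin(2 * pi * 25 * tt) + 2 * sin(2 * pi * 3 * tt), 1)
  d <- decompose(x, g)
  expect_gt(cor(d$imfs[[1]][1, ], sin(2 * pi * 25 * tt)), 0.9)

  expect_error(decompose(matrix(0, 1, 100), g),
               class = "emoselect_graph_error")
})

test_that("product-mode decomposition reconstructs on the coupled graph", {
  mont <- standard_1020_montage(c("F3", "F4", "C3", "C4"))
  g <- build_signal_graph(128, "product", montage = mont, knn = 2)
  set.seed(9)
  x <- matrix(rnorm(4 * 128), 4)
  d <- decompose(x, g, max_imfs = 5)
  expect_lte(d$n_imfs, 5)
  recon <- Reduce(`+`, d$imfs) + d$residual
  expect_lt(sqrt(sum((recon - x)^2) / sum(x^2)), 1e-8)
})

test_that("synthesis mixes the j-th IMF of the j-th contributor", {
  g <- build_signal_graph(256, "temporal")
  set.seed(5)
  xs <- lapply(1:5, function(i) matrix(rnorm(256), 1))
  ds <- lapply(xs, decompose, graph = g, class_label = "high")
  # self-mixing: all contributors the same epoch = sum of its IMFs
  d1 <- ds[[1]]
  self_mix <- synthesize_epoch(rep(list(d1), 5), "high")
  expect_equal(unclass(self_mix)[, ],
               (Reduce(`+`, d1$imfs[seq_len(min(5, d1$n_imfs))]))[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # short contributor slots contribute zero signals
  d_short <- ds[[2]]
  if (d_short$n_imfs >= 1) {
    trunc <- d_short
    trunc$imfs <- trunc$imfs[1]
    trunc$n_imfs <- 1L
    mix <- synthesize_epoch(list(ds[[1]], trunc, trunc, trunc, trunc),
                            "high")
    expect_equal(unclass(mix)[, ], ds[[1]]$imfs[[1]][, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # class purity is enforced
  d_other <- decompose(xs[[3]], g, class_label = "low")
  expect_error(synthesize_epoch(list(ds[[1]], d_other), "high"),
               class = "emoselect_augment_error")
})

test_that("augmentation doubles classes, flags provenance, is seeded", {
  es <- toy_epochs(seed = 21, n_subjects = 2, n_trials = 6,
                   duration = 2, informative_channels = 1,
                   informative_windows = 1, burst_prob = 1)
  y <- epoch_labels(es, "binary_valence")
  aug <- suppressMessages(
    augment_dataset(es, ratio = 1, labels = y, seed = 7))
  expect_equal(n_trials(aug), 2 * n_trials(es))
  expect_equal(sum(aug$meta$augmented), n_trials(es))
  y_aug <- epoch_labels(aug, "binary_valence")
  expect_equal(as.vector(table(y_aug)), 2 * as.vector(table(y)))
  # provenance: no artificial epoch mixes classes
  for (rec in aug$metadata$augmentation_log) {
    expect_equal(length(unique(as.character(y[rec$contributors]))), 1)
    expect_equal(as.character(y[rec$contributors[1]]), rec$class)
  }
  aug2 <- suppressMessages(
    augment_dataset(es, ratio = 1, labels = y, seed = 7))
  expect_identical(aug$data, aug2$data)
  aug3 <- suppressMessages(
    augment_dataset(es, ratio = 1, labels = y, seed = 8))
  expect_false(identical(aug$data, aug3$data))
  # ratio 0 is the identity
  expect_identical(augment_dataset(es, ratio = 0, labels = y), es)
  # too-few epochs per class: skipped with a warning
  tiny <- es[1:4]
  w <- testthat::capture_warnings(
    out <- augment_dataset(tiny, ratio = 1,
                           labels = droplevels(y[1:4]), seed = 1)
  )
  expect_true(all(grepl("fewer than", w)))
  expect_identical(out$data, tiny$data) # both classes skipped
})
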