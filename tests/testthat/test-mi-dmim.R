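test_that("mutual information matches exhaustive enumeration", {
  # independence factorizes to zero
  expect_equal(mutual_information(joint_distribution(
    probs = outer(c(0.3, 0.7), c(0.6, 0.4)))), 0)
  # identical fair binary variables share ln 2 nats
  expect_equal(mutual_information(joint_distribution(
    probs = diag(2) / 2)), log(2))
  # 4-cell joint against the term-by-term sum
  J <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  manual <- sum(J * log(J / outer(rowSums(J), colSums(J))))
  expect_equal(mutual_information(joint_distribution(probs = J)),
               manual, tolerance = 1e-12)
  expect_error(joint_distribution(probs = matrix(c(0.5, 0.2, 0.2, 0.2), 2)),
               class = "emoselect_mi_error")
  expect_error(joint_distribution(probs = matrix(c(-0.1, 0.5, 0.3, 0.3), 2)),
               class = "emoselect_mi_error")

  # random joints with <= 16 cells: exact against enumeration
  for (s in 1:20) {
    set.seed(s)
    r <- sample(2:4, 1); c_ <- sample(2:4, 1)
    J <- matrix(rexp(r * c_), r)
    J <- J / sum(J)
    manual <- 0
    for (i in seq_len(r)) for (j in seq_len(c_)) {
      p <- J[i, j]
      if (p > 0) manual <- manual + p * log(p / (sum(J[i, ]) * sum(J[, j])))
    }
    expect_equal(mutual_information(joint_distribution(probs = J)),
                 manual, tolerance = 1e-12)
  }
})

test_that("empirical MI and conditional MI agree with brute force", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 40
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    cls <- factor(sample(c("x", "y"), n, replace = TRUE))
    expect_equal(emoselect:::mi_discrete(a, b), brute_mi(a, b),
                 tolerance = 1e-12)
    expect_equal(emoselect:::cmi_discrete(a, b, cls),
                 brute_cmi(a, b, cls), tolerance = 1e-12)
    expect_gte(emoselect:::mi_discrete(a, b), 0)
    expect_gte(emoselect:::cmi_discrete(a, b, cls), 0)
  }
})

test_that("DMIM objective decomposes as relevance - redundancy + conditional", {
  set.seed(1)
  n <- 60
  cls <- factor(rep(c("p", "q"), n / 2))
  x1 <- ifelse(cls == "p", 1L, 2L)
  x1[sample(n, 8)] <- sample(1:2, 8, replace = TRUE) # noisy class copy
  x2 <- sample(1:3, n, replace = TRUE)

  # empty selected set: score equals plain relevance
  s0 <- dmim_score(x1, list(), cls)
  expect_equal(s0$score, emoselect:::mi_discrete(x1, cls))
  expect_equal(s0$redundancy, 0)

  # duplicate of a selected feature, independent of the class:
  # relevance ~ 0, redundancy = H(X), conditional = H(X|C) -> score <= 0
  s_dup <- dmim_score(x2, list(x2), cls)
  expect_lte(s_dup$score, 1e-9)
  expect_equal(s_dup$redundancy, brute_mi(x2, x2), tolerance = 1e-12)

  # three-feature toy against term-by-term brute force
  x3 <- ifelse(cls == "p", sample(1:2, n, TRUE), 2L)
  S <- list(x1, x3)
  got <- dmim_score(x2, S, cls)
  exp_score <- brute_mi(x2, cls) -
    max(brute_mi(x2, x1), brute_mi(x2, x3)) +
    max(brute_cmi(x2, x1, cls), brute_cmi(x2, x3, cls))
  expect_equal(got$score, exp_score, tolerance = 1e-12)
})

test_that("greedy ranking starts at max relevance and can exhaust", {
  es <- toy_epochs(seed = 8, duration = 8, n_trials = 10,
                   informative_channels = 1:2, informative_windows = 2:3,
                   burst_prob = 1)
  y <- epoch_labels(es, "binary_valence")
  wf <- window_features(es, 2)
  rk <- dmim_rank(wf, y, k = 4)
  expect_equal(nrow(rk), 4)
  # first pick maximizes plain relevance (empty-set convention)
  rel <- vapply(1:4, function(w) {
    v <- wf |>
      dplyr::filter(window == w) |>
      dplyr::group_by(trial) |>
      dplyr::summarise(de = mean(de)) |>
      dplyr::pull(de)
    emoselect:::mi_discrete(emoselect:::discretize_ef(v, 4), y)
  }, 0)
  expect_equal(rk$window[1], which.max(rel))
  expect_equal(rk$relevance[1], max(rel))
  # exhaustive selection is a permutation of all candidates
  expect_setequal(rk$window, 1:4)
  # per-channel granularity keeps (channel, window) candidates
  rk_cw <- dmim_rank(wf, y, k = 6, granularity = "channel_window")
  expect_true("channel" %in% names(rk_cw))
  expect_equal(nrow(rk_cw), 6)
  expect_error(dmim_rank(wf, factor(rep("one", n_trials(es)))),
               class = "emoselect_dmim_error")
})

test_that("ranking is invariant to positive rescaling of amplitudes", {
  es <- toy_epochs(seed = 12, duration = 8, n_trials = 10,
                   informative_channels = 1:2, informative_windows = c(2, 4),
                   burst_prob = 1)
  y <- epoch_labels(es, "binary_valence")
  rk1 <- dmim_rank(window_features(es, 2), y, k = 4)
  es_scaled <- es
  es_scaled$data <- lapply(es$data, function(m) m * 37.5)
  rk2 <- dmim_rank(window_features(es_scaled, 2), y, k = 4)
  expect_equal(rk1$window, rk2$window)
  expect_equal(rk1$score, rk2$score, tolerance = 1e-9)
})

test_that("accuracy-driven stopping can halt before k", {
  es <- toy_epochs(seed = 13, duration = 8, n_trials = 12,
                   informative_channels = 1:2, informative_windows = 2,
                   burst_prob = 1)
  y <- epoch_labels(es, "binary_valence")
  rk <- dmim_rank(window_features(es, 2), y, k = 4, stop = "accuracy")
  expect_lte(nrow(rk), 4)
  expect_true(all(is.finite(rk$accuracy)))
})
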