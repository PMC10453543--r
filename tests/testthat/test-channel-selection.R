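test_that("equal-frequency discretization fills bins evenly and is deterministic", {
  set.seed(3)
  es <- epoch_set(
    list(matrix(runif(400), 1), matrix(runif(400), 1)),
    "C3", 100, tibble::tibble(subject = 1, trial = 1:2,
                              valence = c(3, 7), arousal = c(5, 6))
  )
  d1 <- discretize(es, n_bins = 4)
  occ <- rowSums(d1$counts[, , 1])
  expect_true(max(occ) - min(occ) <= 1) # equal occupancy up to ties
  d2 <- discretize(es, n_bins = 4)
  expect_identical(d1$bin_edges, d2$bin_edges)
  expect_identical(d1$counts, d2$counts)
  # every sample in exactly one bin
  expect_equal(sum(d1$counts), 800)

  const <- epoch_set(
    list(matrix(1, 1, 100)), "C3", 100,
    tibble::tibble(subject = 1, trial = 1, valence = 4, arousal = 4)
  )
  dc <- discretize(const, n_bins = 4)
  expect_true(dc$constant_channels[1])
  expect_equal(sum(dc$counts[, 1, 1] > 0), 1) # single occupied bin
})

test_that("channel relevance score matches brute-force enumeration", {
  # trials whose symbols all lie inside the class symbol set score 0
  syms <- list(c(1L, 2L), c(1L, 2L), c(2L, 1L))
  disc <- disc_from_symbols(syms, 2)
  labels <- factor(c("a", "a", "b"))
  expect_equal(channel_class_score(disc, labels, 1, "a"), 0)

  # hand enumeration: class symbols {1}; outside trials overlap 1/2
  syms <- list(c(1L, 1L), c(1L, 2L), c(1L, 2L))
  disc <- disc_from_symbols(syms, 2)
  labels <- factor(c("a", "b", "b"))
  # terms: trial1 ratio 1, trials 2-3 ratio 1/2 -> E = 2/3 bit
  expect_equal(channel_class_score(disc, labels, 1, "a"), 2 / 3)
  expect_equal(channel_class_score(disc, labels, 1, "a"),
               brute_channel_score(syms, labels, "a"))

  # zero overlap floors the ratio at 1/(n+1)
  syms <- list(c(1L, 1L, 1L), c(2L, 2L, 2L))
  disc <- disc_from_symbols(syms, 2)
  labels <- factor(c("a", "b"))
  expect_equal(channel_class_score(disc, labels, 1, "a"),
               -mean(log2(c(1, 1 / 4))))

  # randomized toy instances: exact agreement with the brute force
  for (s in 1:10) {
    set.seed(s)
    n_tr <- sample(3:5, 1)
    n_bins <- sample(2:4, 1)
    syms <- lapply(seq_len(n_tr), function(i) {
      sample.int(n_bins, sample(4:8, 1), replace = TRUE)
    })
    labels <- factor(sample(c("a", "b"), n_tr, replace = TRUE))
    if (nlevels(droplevels(labels)) < 2) next
    disc <- disc_from_symbols(syms, n_bins)
    for (cl in c("a", "b")) {
      expect_equal(channel_class_score(disc, labels, 1, cl),
                   brute_channel_score(syms, labels, cl))
    }
  }

  expect_error(
    channel_class_score(disc_from_symbols(list(1L, 2L), 2),
                        factor(c("a", "a")), 1, "zz"),
    class = "emoselect_score_error"
  )
})

test_that("scores are invariant to trial order", {
  es <- toy_epochs(seed = 11, informative_channels = 1:2,
                   informative_windows = 1:2, burst_prob = 1)
  y <- epoch_labels(es, "binary_valence")
  t1 <- score_channels(es, labels = y, n_bins = 8)
  perm <- sample(n_trials(es))
  t2 <- score_channels(es[perm], labels = y[perm], n_bins = 8)
  expect_equal(t1$score, t2$score)
})

test_that("thresholding keeps channels at or above the cut, ranked", {
  tbl <- tibble::tibble(
    channel = rep(c("A", "B", "C"), each = 2),
    class = rep(c("low", "high"), 3),
    score = c(1.1, 1.6, 0.2, 1.4, 1.7, 0.3),
    max_score = rep(c(1.6, 1.4, 1.7), each = 2)
  )
  class(tbl) <- c("channel_score_table", class(tbl))
  sel <- select_channels(tbl, threshold = 1.5)
  expect_equal(sel$channel, c("C", "A")) # descending score
  expect_equal(nrow(select_channels(tbl, threshold = 0)), 3)
  expect_warning(empty <- select_channels(tbl, threshold = 99))
  expect_equal(nrow(empty), 0)
  # monotone: selected-set size non-increasing in the threshold
  sizes <- vapply(seq(0, 2.5, by = 0.25), function(th) {
    nrow(suppressWarnings(select_channels(tbl, th)))
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("common channels intersect selections and cap at k", {
  s1 <- tibble::tibble(channel = c("F3", "F4", "C3"), score = 3:1)
  s2 <- tibble::tibble(channel = c("C3", "F3", "O1"), score = 3:1)
  expect_warning(cc <- common_channels(list(s1, s2), k = 10))
  expect_setequal(cc$channel, c("F3", "C3"))
  # one selection is its own intersection
  expect_equal(common_channels(list(s1), k = 3)$channel, s1$channel)
  # cap to the k best mean ranks
  expect_equal(nrow(common_channels(list(s1, s2), k = 1)), 1)
  expect_equal(common_channels(list(s1, s2), k = 1)$channel, "F3")
  expect_error(
    common_channels(list(c("A", "B"), c("X", "Y"))),
    class = "emoselect_score_error"
  )
})
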