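test_that("LOSO folds partition trials with no subject leakage", {
  es <- toy_epochs(n_subjects = 5, n_trials = 4, duration = 2, seed = 3)
  folds <- loso_splits(es)
  expect_equal(nrow(folds), 5)
  all_test <- sort(unlist(folds$test))
  expect_equal(all_test, seq_len(n_trials(es))) # exact partition
  for (i in seq_len(nrow(folds))) {
    tr_sub <- es$meta$subject[folds$train[[i]]]
    te_sub <- es$meta$subject[folds$test[[i]]]
    expect_length(intersect(tr_sub, te_sub), 0)
    expect_equal(unique(te_sub), folds$subject[i])
  }
  one <- es[es$meta$subject == 1]
  expect_error(loso_splits(one), class = "emoselect_eval_error")
})

test_that("the pipeline is deterministic and reports consistent means", {
  es <- generate_epoch_set(synthetic_spec(
    toy_profile(n_subjects = 3, n_trials = 8, n_channels = 4,
                duration = 4),
    informative_channels = c("C3", "C4"), informative_windows = c(1, 3),
    window_seconds = 1, burst_prob = 1, seed = 17
  ))
  cfg <- pipeline_config(
    task = "binary_valence", n_channels = 2, window_seconds = 1,
    top_windows = 2,
    model = model_config(conv_layers = 2, filters = c(8, 4),
                         kernels = c(5, 3), fc_units = 8,
                         batch_size = 16),
    epochs_override = 4, seed = 11
  )
  r1 <- run_pipeline(es, cfg)
  expect_s3_class(r1, "eval_report")
  expect_equal(nrow(r1$per_fold), 3)
  expect_true(all(r1$per_fold$n_test == 8))
  # summary means equal recomputed per-fold means, exactly
  for (mcol in c("accuracy", "precision", "specificity", "recall",
                 "f1")) {
    expect_identical(r1$summary[[mcol]], mean(r1$per_fold[[mcol]]))
  }
  expect_true(all(r1$per_fold$accuracy >= 0 &
                    r1$per_fold$accuracy <= 1))
  expect_lte(r1$summary$selection_cost, 0)
  r2 <- run_pipeline(es, cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$summary, r2$summary)
})

test_that("augmented epochs never reach test folds", {
  es <- generate_epoch_set(synthetic_spec(
    toy_profile(n_subjects = 3, n_trials = 8, n_channels = 4,
                duration = 4),
    informative_channels = c("C3", "C4"), informative_windows = c(1, 3),
    window_seconds = 1, burst_prob = 1, seed = 19
  ))
  cfg <- pipeline_config(
    task = "binary_valence", n_channels = 2, window_seconds = 1,
    top_windows = 2, augment_ratio = 1,
    model = model_config(conv_layers = 2, filters = c(8, 4),
                         kernels = c(5, 3), fc_units = 8,
                         batch_size = 16),
    epochs_override = 3, seed = 13
  )
  r <- suppressMessages(run_pipeline(es, cfg))
  # each fold's test set is exactly the held-out subject's real trials
  expect_equal(sum(r$per_fold$n_test), n_trials(es))
  expect_equal(sum(r$confusion), n_trials(es))
})

test_that("reports serialize to TSV", {
  es <- generate_epoch_set(synthetic_spec(
    toy_profile(n_subjects = 2, n_trials = 6, n_channels = 4,
                duration = 2),
    informative_channels = 3:4, informative_windows = 1,
    window_seconds = 1, burst_prob = 1, seed = 23
  ))
  cfg <- pipeline_config(
    task = "binary_valence", n_channels = 2, window_seconds = 1,
    top_windows = 1,
    model = model_config(conv_layers = 2, filters = c(4, 2),
                         kernels = c(3, 1), fc_units = 4,
                         batch_size = 8),
    epochs_override = 2, seed = 5
  )
  r <- run_pipeline(es, cfg)
  dir <- withr::local_tempdir()
  write_eval_report(r, dir)
  back <- utils::read.delim(file.path(dir, "report.tsv"))
  expect_equal(nrow(back), nrow(r$per_fold))
  smry <- utils::read.delim(file.path(dir, "summary.tsv"))
  expect_equal(smry$accuracy, r$summary$accuracy)
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(nrow(glance(r)), 1)
})

test_that("autoplot methods return ggplot objects", {
  es <- toy_epochs(seed = 29, informative_channels = 1:2,
                   informative_windows = 1, burst_prob = 1)
  y <- epoch_labels(es, "binary_valence")
  tbl <- score_channels(es, labels = y, n_bins = 8)
  expect_s3_class(autoplot(tbl), "ggplot")
  rk <- dmim_rank(window_features(es, 2), y, k = 2)
  expect_s3_class(autoplot(rk), "ggplot")
  expect_s3_class(autoplot(standard_1020_montage(c("F3", "F4"))),
                  "ggplot")
})
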