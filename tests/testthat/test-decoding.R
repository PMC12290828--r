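# Time-resolved LDA decoding, shuffles, cross-phase generalization.

make_fs <- function(effect, n_trials = 80, n_channels = 16, seed = 1,
                    epoch = c(0, 300)) {
  d <- flat_design(n_trials)
  cfg <- sim_config(n_channels = n_channels, epoch_ms = epoch,
                    effect_uv = effect, noise_rms_uv = 5, osc_amp_uv = 2,
                    onset_mean_ms = mean(epoch),
                    onset_jitter_sd_ms = 15, response_duration_ms = 180,
                    ping_amp_uv = 0, seed = seed)
  zscore_across_channels(gaussian_moving_average(simulate_epochs(d, cfg,
                                                                 "cue")))
}

test_that("label-free data decodes at chance; separable data near AUC 1", {
  dc <- decoder_config(n_repetitions = 2, n_label_shuffles = 2,
                       shuffle_repetitions = 1, seed = 3)
  # independent replicate null datasets: the grand-mean AUC sits at chance
  means <- vapply(1:6, function(s) {
    fs0 <- make_fs(0, n_trials = 60, seed = 20 + s)
    mean(decode_timecourse(fs0, fs0$trials$top, dc)$empirical)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * se + 1e-8)

  fs1 <- make_fs(10, seed = 22)
  d1 <- decode_timecourse(fs1, fs1$trials$top, dc)
  sig <- abs(fs1$window_times - 150) < 60
  expect_gt(max(d1$empirical[sig]), 0.95)
})

test_that("class sizes below the fold count are rejected", {
  fs <- make_fs(0, n_trials = 8, seed = 5)
  expect_error(decode_timecourse(fs, fs$trials$top,
                                 decoder_config(n_folds = 5)),
               "n_folds")
  expect_error(decode_timecourse(fs, rep("a", 8), decoder_config()),
               "2 classes")
})

test_that("rank AUC equals the ROC-integral oracle on small cases", {
  roc_auc <- function(scores, y) {
    # integral of the empirical ROC curve by trapezoid over all thresholds
    thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(scores[y == 2] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(9)
  for (r in 1:20) {
    n <- sample(6:20, 1)
    y <- c(rep(1L, floor(n / 2)), rep(2L, n - floor(n / 2)))
    s <- rnorm(n)
    expect_equal(pingdecode:::rank_auc(s, y), roc_auc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("folds are stratified within one trial of class proportions", {
  set.seed(2)
  y <- rep(1:3, times = c(20, 15, 10))
  folds <- pingdecode:::stratified_folds(y, 5)
  for (f in 1:5) {
    for (c in 1:3) {
      expected <- sum(y == c) / 5
      expect_lte(abs(sum(y[folds == f] == c) - expected), 1)
    }
  }
})

test_that("decoding is invariant to a round-trip trial reordering", {
  fs <- make_fs(5, n_trials = 40, seed = 8)
  dc <- decoder_config(n_repetitions = 1, seed = 4)
  base <- decode_timecourse(fs, fs$trials$top, dc)
  perm <- sample(40)
  back <- subset_features(subset_features(fs, perm), order(perm))
  again <- decode_timecourse(back, back$trials$top, dc)
  expect_identical(base$empirical, again$empirical)
})

test_that("shuffled-label decoding is seeded and centres on chance", {
  fs <- make_fs(8, n_trials = 60, seed = 31)
  dc <- decoder_config(n_repetitions = 1, n_label_shuffles = 100,
                       shuffle_repetitions = 1, seed = 12)
  shf <- shuffled_decode(fs, fs$trials$top, dc)
  expect_equal(dim(shf)[1], 100)
  expect_lt(abs(mean(shf) - 0.5), 0.02)
  shf2 <- shuffled_decode(fs, fs$trials$top, dc)
  expect_identical(unclass(shf), unclass(shf2))
  dc1 <- decoder_config(n_repetitions = 1, n_label_shuffles = 1,
                        shuffle_repetitions = 1, seed = 12)
  expect_equal(nrow(shuffled_decode(fs, fs$trials$top, dc1)), 1)
})

test_that("cross-phase decoding shows training optimism and honours spans", {
  fs <- make_fs(4, n_trials = 60, seed = 41, epoch = c(0, 1200))
  dc <- decoder_config(n_repetitions = 2, seed = 5)
  cv <- decode_timecourse(fs, fs$trials$top, dc)
  cross <- cross_decode(fs, fs$trials$top, fs, fs$trials$top, dc,
                        train_window = c(100, 1000))
  expect_identical(cross$window_times, fs$window_times)
  matched <- fs$window_times >= 100 & fs$window_times <= 1000
  expect_gte(mean(cross$empirical[matched]), mean(cv$empirical[matched]))

  # permuted test labels -> chance
  set.seed(6)
  perm_labels <- sample(fs$trials$top)
  cross0 <- cross_decode(fs, fs$trials$top, fs, perm_labels, dc)
  expect_lt(abs(mean(cross0$empirical) - 0.5), 0.1)

  expect_error(cross_decode(fs, fs$trials$top, fs, fs$trials$top, dc,
                            train_window = c(5000, 6000)),
               "No training windows")
})

test_that("level selection picks the level carrying the signal", {
  h <- build_hierarchy()
  # 64 trials spanning all 16 bottom categories, signal injected at top only
  mk_fs <- function(i, effect) {
    leaf <- h[h$instance == 1, ][rep(1:16, 4), ]
    d <- flat_design(64, labels = leaf$top)
    d$middle <- leaf$middle
    d$bottom <- leaf$bottom
    cfg <- sim_config(n_channels = 8, epoch_ms = c(0, 260),
                      effect_uv = effect, onset_mean_ms = 130,
                      onset_jitter_sd_ms = 10, response_duration_ms = 150,
                      ping_amp_uv = 0, signal_level = "top", seed = 600 + i)
    zscore_across_channels(gaussian_moving_average(simulate_epochs(d, cfg,
                                                                   "cue")))
  }
  dc <- decoder_config(n_folds = 2, n_repetitions = 1, n_label_shuffles = 3,
                       shuffle_repetitions = 1, seed = 2)
  fs_list <- lapply(1:6, mk_fs, effect = 8)
  sel <- level_selection(fs_list, cfg = dc)
  expect_equal(sel$report$n_classes, c(2, 4, 16))
  expect_equal(sel$report$chance, c(1 / 2, 1 / 4, 1 / 16))
  expect_equal(sel$selected, "top")

  # null data: no significant windows at any level
  fs0 <- lapply(1:6, mk_fs, effect = 0)
  sel0 <- level_selection(fs0, cfg = dc)
  expect_equal(sum(sel0$report$n_significant), 0)

  fs_nolab <- fs_list[[1]]
  fs_nolab$trials$bottom <- NULL
  expect_error(level_selection(list(fs_nolab), cfg = dc), "missing")
})
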