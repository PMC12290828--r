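# Stimulus hierarchy and trial-design generator.

test_that("hierarchy has the full nested 2 x 2 x 4 x 12 structure", {
  h <- build_hierarchy()
  expect_equal(nrow(h), 192)
  expect_equal(as.vector(table(h$top)), c(96L, 96L))
  expect_equal(sort(unique(h$top)), c("object", "scene"))
  # 2 middle categories nested per top, 48 leaves each
  mids <- dplyr::count(h, top, middle)
  expect_equal(nrow(mids), 4)
  expect_true(all(mids$n == 48))
  # 4 bottom categories per middle, 12 instances each
  bots <- dplyr::count(h, top, middle, bottom)
  expect_equal(nrow(bots), 16)
  expect_true(all(bots$n == 12))
  expect_false(any(duplicated(h$image_id)))
  # every leaf has exactly one label per level
  expect_true(all(stats::complete.cases(h)))
})

test_that("default design reproduces the experiment's arithmetic", {
  d <- generate_design(seed = 7)
  recall <- d[d$phase == "recall", ]
  expect_equal(nrow(recall), 320)
  expect_equal(sum(d$phase == "encoding"), 80)
  expect_equal(as.vector(table(recall$top)), c(160L, 160L))
  expect_equal(mean(recall$is_ping), 0.75)
  # 80 trials per condition, top-level balanced within each
  tab <- table(recall$condition, recall$top)
  expect_true(all(tab == 40))
  # each pair sees each condition exactly once
  pc <- dplyr::count(recall, pair_id, condition)
  expect_true(all(pc$n == 1))
})

test_that("ping times respect their SOA bins and uniformity within bins", {
  bins <- soa_bins()
  pooled <- c()
  for (s in 1:42) {
    recall <- dplyr::filter(generate_design(seed = s), phase == "recall",
                            is_ping)
    joined <- dplyr::left_join(recall, bins, by = "condition")
    expect_true(all(joined$ping_time_ms >= joined$lo_ms &
                      joined$ping_time_ms <= joined$hi_ms))
    pooled <- c(pooled, (joined$ping_time_ms - joined$lo_ms) /
                  (joined$hi_ms - joined$lo_ms))
  }
  expect_gte(length(pooled), 10000)
  expect_gt(stats::ks.test(pooled, "punif")$p.value, 0.01)
})

test_that("recall order avoids immediate pair repeats within a block", {
  for (s in 1:5) {
    recall <- dplyr::filter(generate_design(n_blocks = 3, seed = s),
                            phase == "recall")
    for (b in unique(recall$block)) {
      ids <- recall$pair_id[recall$block == b][order(
        recall$trial_in_block[recall$block == b])]
      expect_false(any(ids[-1] == ids[-length(ids)]))
    }
  }
  # the forced tiny case: 2 pairs x 4 reps = 8 trials, 2 per condition
  d <- generate_design(n_blocks = 1, n_pairs_per_block = 2, n_reps = 4,
                       seed = 1)
  recall <- d[d$phase == "recall", ]
  expect_equal(nrow(recall), 8)
  expect_true(all(table(recall$condition) == 2))
  ids <- recall$pair_id[order(recall$trial_in_block)]
  expect_false(any(ids[-1] == ids[-8]))
})

test_that("design generation is deterministic and rejects infeasible input", {
  expect_identical(generate_design(seed = 3), generate_design(seed = 3))
  expect_error(generate_design(n_pairs_per_block = 5, seed = 1), "even")
  expect_error(generate_design(n_reps = 3, seed = 1), "multiple")
  expect_error(generate_design(n_blocks = 30, seed = 1), "hierarchy")
})

test_that("pseudo-pings resample the participant's own ping-time pool", {
  # degenerate pool: all pseudo-pings equal the single ping time
  d <- flat_design(40, condition = rep(c("middle", "none"), each = 20),
                   is_ping = rep(c(TRUE, FALSE), each = 20),
                   ping_time_ms = rep(c(1000, NA), each = 20))
  pp <- make_pseudo_pings(d, seed = 1)
  expect_true(all(pp$pseudo_ping_time_ms[!pp$is_ping] == 1000))
  expect_true(all(is.na(pp$pseudo_ping_time_ms[pp$is_ping])))

  # empirical distribution over a 3-point pool is uniform (chi-square GOF)
  n <- 10000
  d <- flat_design(n + 30,
                   condition = c(rep("middle", 30), rep("none", n)),
                   is_ping = c(rep(TRUE, 30), rep(FALSE, n)),
                   ping_time_ms = c(rep(c(600, 900, 1300), 10), rep(NA, n)))
  pp <- make_pseudo_pings(d, seed = 2)
  counts <- table(pp$pseudo_ping_time_ms[!pp$is_ping])
  expect_equal(sort(as.numeric(names(counts))), c(600, 900, 1300))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # determinism and the no-ping-pool error
  expect_identical(make_pseudo_pings(d, seed = 9),
                   make_pseudo_pings(d, seed = 9))
  d0 <- flat_design(10)
  expect_error(make_pseudo_pings(d0, seed = 1), "no ping trials")
})
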