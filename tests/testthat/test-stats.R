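# Two-level permutation, Wilcoxon contrasts, BY-FDR, supplementary analyses.

test_that("two-level permutation honours the add-one convention", {
  # observed above every attainable null mean -> p = 1/(n+1)
  emp <- matrix(2, 3, 1)
  fl <- array(runif(3 * 4), c(3, 4, 1))
  cfg <- stat_config(n_second_level = 999, seed = 1)
  res <- two_level_permutation(emp, fl, cfg, window_times = 0)
  expect_equal(res$p_raw, 1 / 1000)

  # observed at the null median -> p ~ 0.5
  emp <- matrix(0.5, 1, 1)
  fl <- array(c(0, 1), c(1, 2, 1))
  res <- two_level_permutation(emp, fl, stat_config(n_second_level = 4000,
                                                    seed = 2),
                               window_times = 0)
  expect_lt(abs(res$p_raw - 0.5), 0.05)
  expect_gt(res$p_raw, 0)
})

test_that("two-level Monte-Carlo matches exhaustive enumeration (3 x 4)", {
  set.seed(10)
  fl <- array(rnorm(3 * 4), c(3, 4, 2))
  emp <- matrix(rnorm(6, 0.3), 3, 2)
  res <- two_level_permutation(emp, fl, stat_config(n_second_level = 40000,
                                                    seed = 3),
                               window_times = c(0, 1))
  for (w in 1:2) {
    # oracle: enumerate all 4^3 = 64 equally likely draw combinations
    grid <- expand.grid(a = 1:4, b = 1:4, c = 1:4)
    null_means <- apply(grid, 1, function(g) {
      mean(c(fl[1, g[1], w], fl[2, g[2], w], fl[3, g[3], w]))
    })
    exact <- mean(null_means >= mean(emp[, w]))
    expect_lt(abs(res$p_raw[w] - exact), 0.02)
  }
})

test_that("two-level permutation restricts windows and is reproducible", {
  emp <- matrix(rnorm(4 * 10, 0.5, 0.01), 4, 10)
  fl <- array(rnorm(4 * 5 * 10, 0.5, 0.01), c(4, 5, 10))
  wt <- seq(0, 900, by = 100)
  cfg <- stat_config(n_second_level = 500, analysis_window_ms = c(300, 700),
                     seed = 6)
  res <- two_level_permutation(emp, fl, cfg, window_times = wt)
  expect_equal(res$window_time_ms, wt[wt >= 300 & wt <= 700])
  expect_identical(res$p_raw,
                   two_level_permutation(emp, fl, cfg,
                                         window_times = wt)$p_raw)
  expect_true(all(res$p_fdr >= res$p_raw))
  expect_error(
    two_level_permutation(emp, fl,
                          stat_config(analysis_window_ms = c(5000, 6000)),
                          window_times = wt),
    "no decoding windows")
})

test_that("wilcoxon contrast: degenerate, shifted, and exact-oracle cases", {
  a <- matrix(rnorm(29), 29, 1)
  expect_warning(res <- wilcoxon_contrast(a, a, window_times = 0), "zero")
  expect_equal(res$p_raw, 1)

  b <- a - 0.5                    # a = b + 0.5 everywhere
  res <- wilcoxon_contrast(a, b, stat_config(alternative = "greater"),
                           window_times = 0)
  expect_lt(res$p_raw[1], 0.001)

  # exact enumeration oracle at n = 12: all 2^12 sign assignments
  set.seed(33)
  n <- 12
  x <- rnorm(n, 0.3)
  y <- rnorm(n)
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  exact_p <- mean(v_null >= v_obs)
  res <- wilcoxon_contrast(matrix(x), matrix(y),
                           stat_config(alternative = "greater"),
                           window_times = 0)
  expect_equal(res$p_raw, exact_p, tolerance = 1e-12)
})

test_that("wilcoxon p-values are uniform when both samples share a law", {
  set.seed(44)
  ps <- replicate(200, {
    a <- matrix(rnorm(16), 16, 1)
    b <- matrix(rnorm(16), 16, 1)
    suppressWarnings(wilcoxon_contrast(a, b, window_times = 0)$p_raw)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Benjamini-Yekutieli matches the literal step-up formula", {
  expect_equal(fdr_dependent(0.03), 0.03)
  expect_equal(fdr_dependent(numeric(0)), numeric(0))
  expect_equal(fdr_dependent(rep(1, 5)), rep(1, 5))

  p <- c(0.01, 0.02, 0.03, 0.04)
  # literal published step-up: q_i = min_{j >= i} min(1, m * c(m) * p_j / j)
  m <- 4
  cm <- sum(1 / (1:m))
  q <- pmin(1, m * cm * p / seq_len(m))
  q <- rev(cummin(rev(q)))
  expect_equal(fdr_dependent(p), q)
  expect_equal(q[1], 0.01 * 4 * (25 / 12) / 1)

  # idempotent on its own output; monotone above the raw values
  set.seed(5)
  pr <- runif(20)
  adj <- fdr_dependent(pr)
  expect_equal(fdr_dependent(adj), adj)
  expect_true(all(adj >= pr))
  expect_error(fdr_dependent(c(0.5, 0)), "0, 1")
})

test_that("trial-count simulation reproduces the power/null direction", {
  pres <- trial_count_pvalue_simulation(c(40, 160), effect = "present",
                                        n_replicates = 3, seed = 91)
  abst <- trial_count_pvalue_simulation(c(40, 160), effect = "absent",
                                        n_replicates = 3, seed = 92)
  expect_lte(pres$median_p[2], pres$median_p[1])
  expect_lt(pres$median_p[2], 0.1)
  expect_true(all(abst$median_p > 0.05))
  # shuffled-null spread shrinks with trial count in both regimes
  expect_lt(pres$mean_null_sd[2], pres$mean_null_sd[1])
  expect_lt(abst$mean_null_sd[2], abst$mean_null_sd[1])
})

test_that("intertrial variance contrast detects latency regularization", {
  sim_cond <- function(i, rho, is_ping) {
    # one stimulus class: across-trial variance then reflects latency
    # jitter of a shared pattern, the quantity the contrast targets
    d <- cond_design(24, "middle", 700 + i)
    d$is_ping <- is_ping
    d$top <- "object"
    cfg <- sim_config(n_channels = 6, epoch_ms = c(600, 1400), effect_uv = 12,
                      noise_rms_uv = 2, osc_amp_uv = 1, onset_mean_ms = 1000,
                      onset_jitter_sd_ms = 120, response_duration_ms = 250,
                      ping_amp_uv = 0, rho = rho,
                      seed = 700 + i + 1000 * is_ping)
    simulate_epochs(d, cfg, "cue")
  }
  ping <- lapply(1:10, sim_cond, rho = 1, is_ping = TRUE)
  noping <- lapply(1:10, sim_cond, rho = 1, is_ping = FALSE)
  res <- intertrial_variance_contrast(ping, noping, window = c(850, 1250))
  # aligned onsets on pinged trials -> lower across-trial variance
  expect_gt(mean(res$mean_ping < res$mean_noping), 0.5)
  expect_true(any(res$p_fdr < 0.05))

  # identical data in both conditions -> p = 1 everywhere
  same <- intertrial_variance_contrast(ping, ping, window = c(850, 1250))
  expect_true(all(same$p_raw == 1))

  # rho = 0: both conditions share the jitter law, no systematic difference
  ping0 <- lapply(1:10, sim_cond, rho = 0, is_ping = TRUE)
  noping0 <- lapply(1:10, sim_cond, rho = 0, is_ping = FALSE)
  res0 <- intertrial_variance_contrast(ping0, noping0, window = c(850, 1250))
  expect_false(any(res0$p_fdr < 0.05))

  expect_error(
    intertrial_variance_contrast(list(subset_epochs(ping[[1]], 1)),
                                 list(subset_epochs(noping[[1]], 1))),
    "at least 2 trials")
})
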