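# Baseline correction, Gaussian windowing, z-scoring, band power.

test_that("baseline correction subtracts the [start, end) window mean", {
  # constant trace -> all zeros
  ep <- tiny_epochs(array(3, c(2, 2, 250)))
  bc <- baseline_correct(ep, c(-200, 0))
  expect_equal(max(abs(bc$data)), 0)

  # linear ramp x(t) = t: mean over [-200, 0) is the mean of the covered
  # sample times, so the trace is shifted by exactly that amount
  ep <- tiny_epochs(array(0, c(1, 2, 250)))
  ep$data[1, , ] <- rep(ep$times, each = 2)
  bc <- baseline_correct(ep, c(-200, 0))
  covered <- ep$times[ep$times >= -200 & ep$times < 0]
  expect_equal(bc$data[1, 1, ], ep$times - mean(covered))
  sel <- ep$times >= -200 & ep$times < 0
  expect_equal(mean(bc$data[1, 2, sel]), 0)

  expect_error(baseline_correct(ep, c(-2000, 0)), "outside")
  expect_error(baseline_correct(ep, c(0, 100)), "start < end")
})

test_that("gaussian window matches a brute-force convolution oracle", {
  set.seed(42)
  ep <- tiny_epochs(array(rnorm(3 * 2 * 150), c(3, 2, 150)), t0 = -100)
  spec <- window_spec()
  fs <- gaussian_moving_average(ep, spec)

  # independent oracle: explicit loop over windows and samples
  dt <- 4
  n_win <- 35
  h <- (n_win - 1) / 2
  off <- (-h:h) * dt
  sigma <- (h * dt) / sqrt(2 * log(1 / 0.15))
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  starts <- seq(1, 150 - n_win + 1, by = 5)
  for (tr in 1:3) for (ch in 1:2) {
    oracle <- vapply(starts, function(s) {
      sum(ep$data[tr, ch, s:(s + n_win - 1)] * w)
    }, numeric(1))
    expect_lt(max(abs(fs$values[tr, ch, ] - oracle)), 1e-12)
  }
  expect_equal(fs$window_times, ep$times[starts + h])
})

test_that("window geometry: 50 Hz output, 0.15 edge weight, count formula", {
  kern <- pingdecode:::gaussian_kernel(35, 4, 1, 0.15)
  expect_equal(kern$weights[1] / kern$weights[18], 0.15)
  expect_equal(sum(kern$weights), 1)
  # realized FWHM near (not exactly) the nominal ~81 ms
  expect_gt(kern$fwhm, 78)
  expect_lt(kern$fwhm, 86)

  for (n_times in c(100, 137, 250)) {
    ep <- tiny_epochs(array(1, c(1, 2, n_times)), t0 = 0)
    fs <- gaussian_moving_average(ep)
    expect_equal(dim(fs$values)[3], floor((n_times - 35) / 5) + 1)
    expect_equal(unique(diff(fs$window_times)), 20)
    # constant input -> constant output (normalized weights)
    expect_equal(max(abs(fs$values - 1)), 0)
  }
  expect_error(
    gaussian_moving_average(tiny_epochs(array(1, c(1, 2, 20)), t0 = 0)),
    "longer than the epoch")
})

test_that("windowing never leaks across trials and commutes with reordering", {
  set.seed(7)
  ep <- tiny_epochs(array(rnorm(4 * 3 * 100), c(4, 3, 100)), t0 = 0)
  fs <- gaussian_moving_average(ep)
  ep2 <- ep
  ep2$data[2, , ] <- 0
  fs2 <- gaussian_moving_average(ep2)
  expect_identical(fs$values[-2, , ], fs2$values[-2, , ])
  # reordering trials reorders features identically
  perm <- c(3, 1, 4, 2)
  fs3 <- gaussian_moving_average(subset_epochs(ep, perm))
  expect_equal(fs3$values, fs$values[perm, , ])
})

test_that("cross-channel z-scoring standardizes each (trial, window) vector", {
  ep <- tiny_epochs(array(0, c(1, 3, 50)), t0 = 0)
  ep$data[1, , ] <- c(1, 2, 3)
  fs <- zscore_across_channels(gaussian_moving_average(ep))
  # population-SD z-score of (1, 2, 3) is (-1.224745, 0, 1.224745)
  expect_equal(fs$values[1, , 1], c(-1, 0, 1) * 1.224745, tolerance = 1e-6)
  # idempotent on standardized input
  fs2 <- zscore_across_channels(fs)
  expect_equal(fs2$values, fs$values, tolerance = 1e-12)
  # all-equal vectors become zeros with a warning
  ep$data[1, , ] <- 5
  expect_warning(fz <- zscore_across_channels(gaussian_moving_average(ep)),
                 "zero variance")
  expect_true(all(fz$values == 0))
  # general property at random input
  set.seed(1)
  ep <- tiny_epochs(array(rnorm(5 * 6 * 80), c(5, 6, 80)), t0 = 0)
  fz <- zscore_across_channels(gaussian_moving_average(ep))
  for (w in c(1, 4)) {
    expect_lt(max(abs(apply(fz$values[, , w], 1, mean))), 1e-10)
    sds <- apply(fz$values[, , w], 1, function(x) sqrt(mean((x - mean(x))^2)))
    expect_lt(max(abs(sds - 1)), 1e-10)
  }
})

test_that("hilbert band power recovers the analytic envelope of sinusoids", {
  A <- 3
  mk <- function(freq) {
    ep <- tiny_epochs(array(0, c(1, 4, 500)),
                      channels = c("Cz", "Pz", "Oz", "P3"))
    for (ch in 1:4) ep$data[1, ch, ] <- A * sin(2 * pi * freq * ep$times / 1000)
    ep
  }
  fs <- hilbert_band_power(mk(10), zscore = FALSE)
  mid <- abs(fs$window_times + 300) < 250   # central segment, away from edges
  alpha <- grepl("alpha", fs$feature_names)
  theta <- grepl("theta", fs$feature_names)
  beta <- grepl("beta", fs$feature_names)
  gamma <- grepl("gamma", fs$feature_names)
  p_alpha <- mean(fs$values[1, alpha, mid])
  expect_lt(abs(p_alpha - A^2) / A^2, 0.05)

  fs50 <- hilbert_band_power(mk(50), zscore = FALSE)
  p <- vapply(list(theta, alpha, beta, gamma),
              function(b) mean(fs50$values[1, b, mid]), numeric(1))
  expect_gt(p[4] / max(p[1:3]), 10)

  # zero input -> zero power everywhere
  fs0 <- hilbert_band_power(tiny_epochs(array(0, c(1, 4, 500))),
                            zscore = FALSE)
  expect_equal(max(abs(fs0$values)), 0)

  # feature count and Nyquist guard
  expect_equal(dim(fs$values)[2], 4 * 4)
  expect_error(hilbert_band_power(mk(10), band_spec(gamma = c(35, 130))),
               "Nyquist")
})
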