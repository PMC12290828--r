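# Feature extraction: baseline correction, Gaussian-weighted moving-average
# downsampling, cross-channel z-scoring, and Hilbert band-power features.

#' Moving-window specification
#'
#' The decoding features are built by sliding a Gaussian-weighted averaging
#' window along the epoch. The kernel's centre sample has weight
#' `center_weight` and its edge samples `tail_weight`; the Gaussian sigma is
#' solved from that edge condition, `exp(-e^2 / (2 sigma^2)) =
#' tail_weight / center_weight` with `e` the edge-sample offset in ms.
#'
#' @param length_ms Window length in ms (default 140).
#' @param step_ms Step between window centres in ms (default 20, i.e. a 50 Hz
#'   decoding time course).
#' @param center_weight,tail_weight Kernel weights at the centre and edge
#'   samples before normalization.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(length_ms = 140, step_ms = 20,
                        center_weight = 1, tail_weight = 0.15) {
  check_number(length_ms, "length_ms", lower = .Machine$double.eps)
  check_number(step_ms, "step_ms", lower = .Machine$double.eps)
  if (length_ms < step_ms) abort("`length_ms` must be >= `step_ms`.")
  check_number(tail_weight, "tail_weight", lower = .Machine$double.eps,
               upper = center_weight)
  structure(list(length_ms = length_ms, step_ms = step_ms,
                 center_weight = center_weight, tail_weight = tail_weight),
            class = "window_spec")
}

#' Frequency bands for spectral features
#'
#' @param theta,alpha,beta,gamma `(low, high)` band edges in Hz.
#' @return Named list of class `band_spec`.
#' @export
band_spec <- function(theta = c(3, 7), alpha = c(8, 12), beta = c(13, 30),
                      gamma = c(35, 80)) {
  bands <- list(theta = theta, alpha = alpha, beta = beta, gamma = gamma)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2]) {
      abort(sprintf("Band `%s` must satisfy 0 < low < high.", nm))
    }
  }
  structure(bands, class = "band_spec")
}

new_feature_series <- function(values, window_times, feature_names,
                               provenance, trials, zscored = FALSE,
                               fwhm_ms = NA_real_) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[2] == length(feature_names),
            dim(values)[3] == length(window_times))
  structure(list(values = values, window_times = window_times,
                 feature_names = feature_names, provenance = provenance,
                 trials = trials, zscored = zscored, fwhm_ms = fwhm_ms),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d trials x %d features x %d windows (%s%s)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$provenance, if (x$zscored) ", z-scored" else ""))
  cat(sprintf("  window centres %g..%g ms", min(x$window_times),
              max(x$window_times)))
  if (is.finite(x$fwhm_ms)) cat(sprintf("; kernel FWHM %.1f ms", x$fwhm_ms))
  cat("\n")
  invisible(x)
}

#' Subset a feature series by trial
#'
#' @param fs A `feature_series`.
#' @param idx Logical or integer trial index.
#' @return The subset `feature_series`.
#' @export
subset_features <- function(fs, idx) {
  new_feature_series(fs$values[idx, , , drop = FALSE], fs$window_times,
                     fs$feature_names, fs$provenance,
                     fs$trials[idx, , drop = FALSE], fs$zscored, fs$fwhm_ms)
}

#' Convert a feature series to a long tibble
#'
#' @param x A `feature_series`.
#' @param ... Unused.
#' @return Tibble with `trial_id`, `feature`, `window_time_ms`, `value`.
#' @method as_tibble feature_series
#' @export
as_tibble.feature_series <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    trial_id = rep(x$trials$trial_id, times = d[2] * d[3]),
    feature = rep(rep(x$feature_names, each = d[1]), times = d[3]),
    window_time_ms = rep(x$window_times, each = d[1] * d[2]),
    value = as.vector(x$values)
  )
}

#' Baseline-correct epoched EEG
#'
#' Subtracts, per trial and channel, the mean amplitude over the half-open
#' baseline window `[start, end)` from the whole epoch.
#'
#' @param epochs An `eeg_epochs` object.
#' @param window `c(start_ms, end_ms)` with `start < end <= 0`, inside the
#'   epoch.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  if (length(window) != 2L || window[1] >= window[2] || window[2] > 0) {
    abort("Baseline `window` must be c(start, end) with start < end <= 0.")
  }
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel) || window[1] < min(epochs$times)) {
    abort(sprintf("Baseline window [%g, %g) lies outside the epoch (%g..%g ms).",
                  window[1], window[2], min(epochs$times), max(epochs$times)))
  }
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl) # recycles over time (last dim)
  epochs
}

# Gaussian kernel weights for a window of n_win samples at dt ms spacing.
gaussian_kernel <- function(n_win, dt, center_weight, tail_weight) {
  h <- (n_win - 1) / 2
  off <- (-h:h) * dt
  e <- h * dt
  sigma <- e / sqrt(2 * log(center_weight / tail_weight))
  w <- center_weight * exp(-off^2 / (2 * sigma^2))
  list(weights = w / sum(w), sigma = sigma,
       fwhm = 2 * sqrt(2 * log(2)) * sigma)
}

# Shared sliding-window machinery: weighted average of a trial x feature x
# time array over fully covered windows. Returns values plus window times.
window_array <- function(data, times, sfreq, spec) {
  dt <- 1000 / sfreq
  n_times <- length(times)
  n_win <- 2 * floor(spec$length_ms / (2 * dt)) + 1
  if (n_win > n_times) {
    abort("Window is longer than the epoch.")
  }
  step <- spec$step_ms / dt
  if (abs(step - round(step)) > 1e-8) {
    abort("`step_ms` must be an integer number of samples at this sampling rate.")
  }
  step <- as.integer(round(step))
  kern <- gaussian_kernel(n_win, dt, spec$center_weight, spec$tail_weight)
  starts <- seq.int(1L, n_times - n_win + 1L, by = step)
  centers <- starts + (n_win - 1L) / 2
  W <- matrix(0, n_times, length(starts))
  for (j in seq_along(starts)) {
    W[starts[j]:(starts[j] + n_win - 1L), j] <- kern$weights
  }
  d <- dim(data)
  flat <- matrix(data, d[1] * d[2], d[3])
  out <- flat %*% W
  list(values = array(out, c(d[1], d[2], length(starts))),
       window_times = times[centers], fwhm = kern$fwhm)
}

#' Gaussian-weighted moving-average downsampling
#'
#' Slides a `length_ms` window in `step_ms` steps along the epoch and emits,
#' for every fully covered window, the Gaussian-weighted mean (weights
#' normalized to sum 1), producing features at `1000 / step_ms` Hz. With the
#' defaults this converts 250 Hz voltage data into a 50 Hz decoding time
#' course. The realized kernel FWHM is stored on the result (`fwhm_ms`).
#'
#' @param epochs An `eeg_epochs` object.
#' @param spec A [window_spec()].
#' @return A `feature_series` (provenance "voltage") whose features are the
#'   channels.
#' @export
gaussian_moving_average <- function(epochs, spec = window_spec()) {
  w <- window_array(epochs$data, epochs$times, epochs$sfreq, spec)
  if (isTRUE(getOption("pingdecode.verbose", FALSE))) {
    inform(sprintf("Gaussian window kernel: realized FWHM %.1f ms", w$fwhm))
  }
  new_feature_series(w$values, w$window_times, epochs$channels, "voltage",
                     epochs$trials, fwhm_ms = w$fwhm)
}

#' Z-score features across channels
#'
#' For every (trial, window) pair, centres and scales the feature vector to
#' mean 0 and population (n-denominator) SD 1 across features. Zero-variance
#' vectors become all zeros with a warning rather than NaN.
#'
#' @param fs A `feature_series` with at least 2 features.
#' @return The standardized `feature_series`.
#' @export
zscore_across_channels <- function(fs) {
  d <- dim(fs$values)
  if (d[2] < 2L) abort("z-scoring across channels needs at least 2 features.")
  x <- matrix(aperm(fs$values, c(2, 1, 3)), d[2])   # features x (trial*window)
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2)
  degenerate <- s <= 1e-12
  if (any(degenerate)) {
    warn(sprintf("%d of %d (trial, window) vectors have zero variance; set to 0.",
                 sum(degenerate), length(s)))
    s[degenerate] <- Inf
  }
  z <- (x - rep(mu, each = d[2])) / rep(s, each = d[2])
  fs$values <- aperm(array(z, c(d[2], d[1], d[3])), c(2, 1, 3))
  fs$zscored <- TRUE
  fs
}

# analytic-signal envelope via FFT, columns of a time x series matrix
analytic_envelope <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(mvfft(mvfft(x) * h, inverse = TRUE) / n)
}

#' Hilbert band-power features
#'
#' For each frequency band, band-pass filters the data (zero-phase two-pass
#' Butterworth, order `order`), takes the analytic-signal envelope via the
#' Hilbert transform, squares it to power, and passes the power through the
#' same Gaussian windowing (and optional cross-feature z-scoring) as the
#' voltage features. Features are all channel x band combinations.
#'
#' @param epochs An `eeg_epochs` object.
#' @param bands A [band_spec()]; every band must lie below the Nyquist
#'   frequency.
#' @param spec A [window_spec()].
#' @param order Butterworth filter order (default 4; applied forwards and
#'   backwards, so the effective order doubles).
#' @param zscore Standardize across features per (trial, window) (default
#'   TRUE, matching the decoding pipeline).
#' @return A `feature_series` (provenance "band-power") with
#'   `n_channels * n_bands` features named `channel.band`.
#' @export
hilbert_band_power <- function(epochs, bands = band_spec(),
                               spec = window_spec(), order = 4,
                               zscore = TRUE) {
  nyq <- epochs$sfreq / 2
  for (nm in names(bands)) {
    if (bands[[nm]][2] >= nyq) {
      abort(sprintf("Band `%s` (%g-%g Hz) reaches the Nyquist frequency (%g Hz).",
                    nm, bands[[nm]][1], bands[[nm]][2], nyq))
    }
  }
  d <- dim(epochs$data)
  flat <- t(matrix(epochs$data, d[1] * d[2], d[3]))  # time x (trial*channel)
  per_band <- purrr::imap(as.list(bands), function(b, nm) {
    bf <- signal::butter(order, b / nyq, type = "pass")
    filt <- apply(flat, 2, function(v) signal::filtfilt(bf, v))
    env <- analytic_envelope(filt)
    array(t(env^2), c(d[1], d[2], d[3]))
  })
  windowed <- purrr::map(per_band, window_array, times = epochs$times,
                         sfreq = epochs$sfreq, spec = spec)
  vals <- array(0, c(d[1], d[2] * length(bands),
                     length(windowed[[1]]$window_times)))
  for (k in seq_along(windowed)) {
    vals[, (k - 1) * d[2] + seq_len(d[2]), ] <- windowed[[k]]$values
  }
  feats <- as.vector(t(outer(names(bands), epochs$channels,
                             function(b, ch) paste(ch, b, sep = "."))))
  fs <- new_feature_series(vals, windowed[[1]]$window_times, feats,
                           "band-power", epochs$trials,
                           fwhm_ms = windowed[[1]]$fwhm)
  if (zscore) zscore_across_channels(fs) else fs
}
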