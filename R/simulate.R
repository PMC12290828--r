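# Synthetic epoched-EEG generator: 1/f + oscillatory background noise, a
# ping-evoked posterior response, and category-specific multivariate patterns
# whose onset latency jitters across trials. The `rho` parameter shrinks the
# onset jitter on ping trials, embodying the hypothesis that pings regularize
# neural dynamics across trials.

#' Posterior channel set
#'
#' The posterior/centro-parietal channels over which ERP traces are averaged.
#'
#' @return Character vector of 10--20-system channel names.
#' @export
posterior_channels <- function() {
  c("C3", "C4", "P3", "P4", "O1", "O2", "Cz", "Pz", "Oz", "CP1", "CP2",
    "C1", "C2", "P1", "P2", "CP3", "CP4", "PO3", "PO4", "PO7", "PO8",
    "CPz", "POz")
}

default_montage <- function(n_channels) {
  all <- c(posterior_channels(),
           "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
           "FC6", "T7", "C5", "C6", "T8", "AFz", "F1", "F2", "FC3", "FC4",
           "FT7", "FT8", "AF3", "AF4")
  if (n_channels > length(all)) {
    abort(sprintf("Default montage provides at most %d channels.", length(all)))
  }
  all[seq_len(n_channels)]
}

#' Simulation configuration
#'
#' Parameters of the synthetic EEG signal model. Amplitudes are in microvolts,
#' times in milliseconds.
#'
#' @param n_channels Number of EEG channels (named from a 10--20 montage with
#'   posterior channels first).
#' @param sfreq Sampling rate in Hz (default 250; must exceed twice the
#'   highest analysed band edge, 80 Hz).
#' @param epoch_ms Epoch window relative to the lock event, `c(start, end)`
#'   with `end` exclusive (default -1000..3000 ms, i.e. 4 s).
#' @param noise_exponent Spectral exponent of the 1/f background noise.
#' @param noise_rms_uv RMS amplitude of the 1/f noise per channel.
#' @param osc_freq_hz,osc_amp_uv Frequency and amplitude of the background
#'   oscillation (random phase per trial and channel).
#' @param effect_uv Amplitude of the category-specific pattern; 0 yields
#'   label-free null data.
#' @param signal_level Hierarchy level whose labels carry the pattern
#'   ("top", "middle" or "bottom").
#' @param onset_mean_ms,onset_jitter_sd_ms Mean and across-trial SD of the
#'   reinstatement onset latency (cue-locked, recall phase).
#' @param onset_relative_to For recall trials, whether pattern onsets are
#'   expressed relative to the retrieval `"cue"` or to the trial's `"ping"`
#'   time (no-ping trials then fall back to the cue reference).
#' @param response_duration_ms Duration of the half-cosine pattern envelope.
#' @param encoding_onset_mean_ms,encoding_onset_jitter_sd_ms Onset model for
#'   encoding-phase (image-locked) trials.
#' @param ping_amp_uv Amplitude of the ping-evoked biphasic kernel (0 disables
#'   it).
#' @param ping_latency_ms Latency of the first (positive) evoked peak after
#'   ping onset.
#' @param ping_posterior_weight,ping_other_weight Topography weights of the
#'   evoked kernel on posterior vs remaining channels.
#' @param rho Latency-regularization strength in `[0, 1]`: onset jitter SD on
#'   ping trials is multiplied by `1 - rho`.
#' @param seed Integer master seed; design, noise, latency and pattern draws
#'   use independent named substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 32, sfreq = 250, epoch_ms = c(-1000, 3000),
                       noise_exponent = 1, noise_rms_uv = 10,
                       osc_freq_hz = 10, osc_amp_uv = 5,
                       effect_uv = 2, signal_level = "top",
                       onset_mean_ms = 900, onset_jitter_sd_ms = 150,
                       onset_relative_to = c("cue", "ping"),
                       response_duration_ms = 300,
                       encoding_onset_mean_ms = 150,
                       encoding_onset_jitter_sd_ms = 40,
                       ping_amp_uv = 8, ping_latency_ms = 250,
                       ping_posterior_weight = 1, ping_other_weight = 0.2,
                       rho = 0, seed = 1) {
  check_number(rho, "rho", 0, 1)
  check_number(sfreq, "sfreq", lower = .Machine$double.eps)
  if (sfreq <= 2 * 80) {
    abort("`sfreq` must exceed twice the highest analysed band edge (80 Hz).")
  }
  if (length(epoch_ms) != 2L || epoch_ms[1] >= epoch_ms[2]) {
    abort("`epoch_ms` must be c(start, end) with start < end.")
  }
  structure(list(
    n_channels = check_count(n_channels, "n_channels"),
    channels = default_montage(n_channels),
    sfreq = sfreq, epoch_ms = as.numeric(epoch_ms),
    noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv,
    osc_freq_hz = osc_freq_hz, osc_amp_uv = osc_amp_uv,
    effect_uv = effect_uv, signal_level = match.arg(signal_level,
                                                    c("top", "middle", "bottom")),
    onset_mean_ms = onset_mean_ms, onset_jitter_sd_ms = onset_jitter_sd_ms,
    onset_relative_to = match.arg(onset_relative_to),
    response_duration_ms = response_duration_ms,
    encoding_onset_mean_ms = encoding_onset_mean_ms,
    encoding_onset_jitter_sd_ms = encoding_onset_jitter_sd_ms,
    ping_amp_uv = ping_amp_uv, ping_latency_ms = ping_latency_ms,
    ping_posterior_weight = ping_posterior_weight,
    ping_other_weight = ping_other_weight,
    rho = rho, seed = seed
  ), class = "sim_config")
}

new_eeg_epochs <- function(data, times, sfreq, channels, lock, trials) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[1] == nrow(trials),
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times))
  structure(list(data = data, times = times, sfreq = sfreq,
                 channels = channels, lock = lock, trials = as_tibble(trials)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  cat(sprintf("  lock: %s; time %g..%g ms\n", x$lock,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Convert epochs to a long tibble
#'
#' @param x An `eeg_epochs` object.
#' @param ... Unused.
#' @return A tibble with columns `trial_id`, `channel`, `time_ms`,
#'   `amplitude_uv` (one row per sample).
#' @method as_tibble eeg_epochs
#' @export
as_tibble.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial_id = rep(x$trials$trial_id, times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time_ms = rep(x$times, each = d[1] * d[2]),
    amplitude_uv = as.vector(x$data)
  )
}

#' Subset epochs by trial
#'
#' @param epochs An `eeg_epochs` object.
#' @param idx Logical or integer trial index.
#' @return An `eeg_epochs` with the selected trials (metadata subset in step).
#' @export
subset_epochs <- function(epochs, idx) {
  new_eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$times,
                 epochs$sfreq, epochs$channels, epochs$lock,
                 epochs$trials[idx, , drop = FALSE])
}

#' Simulate epoched EEG for a trial design
#'
#' Generates a trial x channel x time voltage tensor for the given design and
#' lock event. Each trial contains: (i) 1/f background noise plus a
#' random-phase oscillation; (ii) for ping trials, a biphasic evoked kernel at
#' the trial's ping time on posterior-weighted channels; (iii) a
#' category-specific channel pattern (fixed unit-norm weight vector per class
#' of `config$signal_level`) scaled by a half-cosine envelope whose onset is
#' drawn per trial from `Normal(onset_mean, jitter_sd * (1 - rho * is_ping))`.
#' Identical `config$seed` yields identical output.
#'
#' @param design Trial table from [generate_design()] (optionally after
#'   [make_pseudo_pings()]).
#' @param config A [sim_config()].
#' @param lock Event defining t = 0: `"cue"` (recall trials), `"ping"`
#'   (recall trials, locked to real ping or pseudo-ping times), or
#'   `"encoding_image"` (encoding trials).
#' @return An `eeg_epochs` object carrying the matching rows of `design` as
#'   trial metadata.
#' @export
simulate_epochs <- function(design, config = sim_config(),
                            lock = c("cue", "ping", "encoding_image")) {
  lock <- match.arg(lock)
  cfg <- config
  if (cfg$sfreq <= 0) abort("`sfreq` must be positive.")

  if (lock == "encoding_image") {
    trials <- design[design$phase == "encoding", , drop = FALSE]
    lock_offset <- rep(0, nrow(trials))
  } else {
    trials <- design[design$phase == "recall", , drop = FALSE]
    if (lock == "cue") {
      lock_offset <- rep(0, nrow(trials))
    } else {
      has_pseudo <- "pseudo_ping_time_ms" %in% names(trials)
      lock_offset <- trials$ping_time_ms
      if (has_pseudo) {
        lock_offset[is.na(lock_offset)] <-
          trials$pseudo_ping_time_ms[is.na(lock_offset)]
      }
      if (anyNA(lock_offset)) {
        abort(paste0("lock = \"ping\" requires ping times on every recall ",
                     "trial; run make_pseudo_pings() to assign pseudo-ping ",
                     "times to no-ping trials."))
      }
    }
  }
  n_trials <- nrow(trials)
  if (n_trials == 0L) abort("No trials for the requested lock/phase.")

  dt <- 1000 / cfg$sfreq
  n_times <- round((cfg$epoch_ms[2] - cfg$epoch_ms[1]) / dt)
  times <- cfg$epoch_ms[1] + (seq_len(n_times) - 1) * dt
  n_ch <- cfg$n_channels

  labels <- trials[[cfg$signal_level]]
  classes <- sort(unique(labels))

  # class pattern vectors: fixed unit-norm channel weights per class
  patterns <- with_seed(substream_seed(cfg$seed, "pattern"), {
    m <- matrix(rnorm(length(classes) * n_ch), length(classes), n_ch)
    m / sqrt(rowSums(m^2))
  })
  rownames(patterns) <- classes

  # onset latencies per trial
  enc <- identical(lock, "encoding_image")
  onset_mean <- if (enc) cfg$encoding_onset_mean_ms else cfg$onset_mean_ms
  onset_sd_base <- if (enc) cfg$encoding_onset_jitter_sd_ms else cfg$onset_jitter_sd_ms
  sd_trial <- onset_sd_base * (1 - cfg$rho * as.numeric(!enc & trials$is_ping))
  onsets <- with_seed(substream_seed(cfg$seed, "latency"), {
    onset_mean + rnorm(n_trials) * sd_trial
  })
  if (!enc && cfg$onset_relative_to == "ping") {
    onsets <- onsets + dplyr::coalesce(trials$ping_time_ms, 0)
  }

  ping_w <- ifelse(cfg$channels %in% posterior_channels(),
                   cfg$ping_posterior_weight, cfg$ping_other_weight)

  data <- array(0, dim = c(n_trials, n_ch, n_times))
  with_seed(substream_seed(cfg$seed, "noise"), {
    for (i in seq_len(n_trials)) {
      x <- one_over_f_noise(n_times, n_ch, cfg$sfreq, cfg$noise_exponent,
                            cfg$noise_rms_uv)
      if (cfg$osc_amp_uv > 0) {
        ph <- runif(n_ch, 0, 2 * pi)
        x <- x + cfg$osc_amp_uv *
          sin(outer(2 * pi * cfg$osc_freq_hz * times / 1000, ph, "+"))
      }
      # grid in event-relative time of the generative model (cue onset for
      # recall, image onset for encoding)
      g <- times + lock_offset[i]
      if (!enc && trials$is_ping[i] && cfg$ping_amp_uv > 0) {
        tau <- g - trials$ping_time_ms[i]
        k <- evoked_kernel(tau, cfg$ping_amp_uv, cfg$ping_latency_ms)
        x <- x + outer(k, ping_w)
      }
      if (cfg$effect_uv > 0) {
        tau <- g - onsets[i]
        env <- half_cosine_env(tau, cfg$response_duration_ms)
        if (any(env > 0)) {
          x <- x + cfg$effect_uv * outer(env, patterns[labels[i], ])
        }
      }
      data[i, , ] <- t(x)
    }
  })
  new_eeg_epochs(data, times, cfg$sfreq, cfg$channels, lock, trials)
}

# 1/f noise, one column per channel, scaled to the requested RMS.
one_over_f_noise <- function(n_times, n_ch, sfreq, exponent, rms) {
  freqs <- seq(0, sfreq / 2, length.out = floor(n_times / 2) + 1)
  amp <- c(0, freqs[-1]^(-exponent / 2))
  ph <- matrix(runif(length(amp) * n_ch, 0, 2 * pi), length(amp), n_ch)
  half <- amp * exp(1i * ph)
  # assemble a Hermitian spectrum so the inverse transform is real
  spec <- rbind(half,
                Conj(half[seq(ifelse(n_times %% 2 == 0, nrow(half) - 1, nrow(half)),
                              2), , drop = FALSE]))
  x <- Re(mvfft(spec[seq_len(n_times), , drop = FALSE], inverse = TRUE))
  sds <- sqrt(colMeans(x^2))
  sds[sds == 0] <- 1
  sweep(x, 2, rms / sds, "*")
}

# Biphasic canonical evoked waveform: positive posterior peak at `latency` ms
# after the event, followed by a shallower negative rebound.
evoked_kernel <- function(tau, amp, latency) {
  out <- amp * (exp(-(tau - latency)^2 / (2 * 60^2)) -
                  0.6 * exp(-(tau - latency - 180)^2 / (2 * 90^2)))
  out[tau < 0] <- 0
  out
}

half_cosine_env <- function(tau, duration) {
  env <- numeric(length(tau))
  inside <- tau >= 0 & tau <= duration
  env[inside] <- sin(pi * tau[inside] / duration)
  env
}
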