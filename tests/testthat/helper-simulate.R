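# Shared fixtures: all built in code at test time.

# minimal epochs container around a given array
tiny_epochs <- function(data, sfreq = 250, t0 = -1000,
                        channels = sprintf("ch%02d", seq_len(dim(data)[2])),
                        trials = NULL, lock = "cue") {
  n <- dim(data)[3]
  times <- t0 + (seq_len(n) - 1) * 1000 / sfreq
  if (is.null(trials)) {
    trials <- tibble::tibble(trial_id = seq_len(dim(data)[1]))
  }
  structure(list(data = data, times = times, sfreq = sfreq,
                 channels = channels, lock = lock, trials = trials),
            class = "eeg_epochs")
}

# bare-bones recall trial table for ad-hoc simulations
flat_design <- function(n_trials, condition = "none", is_ping = FALSE,
                        ping_time_ms = NA_real_, labels = NULL) {
  tibble::tibble(
    trial_id = seq_len(n_trials), phase = "recall", block = 1L,
    trial_in_block = seq_len(n_trials), pair_id = NA_character_,
    condition = condition, is_ping = is_ping, ping_time_ms = ping_time_ms,
    image_id = NA_character_,
    top = labels %||% rep_len(c("object", "scene"), n_trials),
    middle = NA_character_, bottom = NA_character_, instance = NA_integer_
  )
}

`%||%` <- rlang::`%||%`

# recall design for one SOA condition, all trials pinged uniformly in-bin
cond_design <- function(n_trials, cond, seed) {
  bins <- soa_bins()
  b <- bins[bins$condition == cond, ]
  set.seed(seed)
  flat_design(n_trials, condition = cond, is_ping = TRUE,
              ping_time_ms = runif(n_trials, b$lo_ms, b$hi_ms))
}

# mixed ping/no-ping design with uniform ping times over the full range
mix_design <- function(n_trials, seed) {
  set.seed(seed)
  is_ping <- rep(c(TRUE, FALSE), each = n_trials / 2)
  d <- flat_design(n_trials,
                   condition = ifelse(is_ping, "middle", "none"),
                   is_ping = is_ping)
  d$ping_time_ms[is_ping] <- runif(sum(is_ping), 500, 1500)
  d
}

# decode one participant's SOA-specific series + shuffled pools; returns
# list(empirical = 3 x W, shuffled = 3 x K x W)
decode_soa_participant <- function(i, seed0, n_trials = 24, effect_uv = 8,
                                   wspec = window_spec(step_ms = 40),
                                   dc = decoder_config(n_repetitions = 1,
                                                       n_label_shuffles = 8,
                                                       shuffle_repetitions = 1)) {
  emp <- NULL; shf <- NULL
  for (ci in 1:3) {
    cond <- c("early", "middle", "late")[ci]
    sd <- seed0 + i * 17 + ci
    d <- cond_design(n_trials, cond, sd)
    cfg <- sim_config(n_channels = 8, epoch_ms = c(400, 1900),
                      effect_uv = effect_uv, noise_rms_uv = 5,
                      osc_amp_uv = 2, onset_mean_ms = 150,
                      onset_jitter_sd_ms = 30, onset_relative_to = "ping",
                      response_duration_ms = 300, ping_amp_uv = 2, seed = sd)
    ep <- simulate_epochs(d, cfg, lock = "cue")
    fz <- zscore_across_channels(gaussian_moving_average(ep, wspec))
    dci <- dc; dci$seed <- sd
    dtc <- decode_timecourse(fz, fz$trials$top, dci)
    sh <- shuffled_decode(fz, fz$trials$top, dci)
    if (is.null(emp)) {
      emp <- matrix(NA_real_, 3, length(dtc$empirical))
      shf <- array(NA_real_, c(3, nrow(sh), ncol(sh)))
    }
    emp[ci, ] <- dtc$empirical
    shf[ci, , ] <- sh
  }
  list(empirical = emp, shuffled = shf)
}

# group-level POD inputs with SOA-ordered reinstatement onsets
build_pod_arrays <- function(n_participants, seed0, effect_uv = 8) {
  emp <- NULL; shf <- NULL
  for (i in seq_len(n_participants)) {
    pr <- decode_soa_participant(i, seed0, effect_uv = effect_uv)
    if (is.null(emp)) {
      emp <- array(NA_real_, c(n_participants, dim(pr$empirical)))
      shf <- array(NA_real_, c(n_participants, dim(pr$shuffled)))
    }
    emp[i, , ] <- pr$empirical
    shf[i, , , ] <- pr$shuffled
  }
  list(empirical = emp, shuffled = shf)
}
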