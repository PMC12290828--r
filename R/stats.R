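# Group-level inference: two-level Monte-Carlo permutation testing, Wilcoxon
# signed-rank contrasts, FDR under dependence, and the supplementary
# trial-count and intertrial-variance analyses.

#' Statistics configuration
#'
#' @param n_second_level Second-level Monte-Carlo draws (default 1e5; the POD
#'   test uses its own default of 1e6).
#' @param alpha Significance level (default 0.05).
#' @param analysis_window_ms `c(lo, hi)` ms restricting which windows are
#'   tested (applied before FDR). Use `analysis_window("ping")` (0--500 ms)
#'   or `analysis_window("cue")` (500--2000 ms), or `NULL` for all windows.
#' @param alternative Sidedness: `"greater"` (empirical above null; decoding
#'   tests), `"less"`, or `"two.sided"`.
#' @param seed Seed for the Monte-Carlo draws.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(n_second_level = 1e5, alpha = 0.05,
                        analysis_window_ms = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        seed = 1) {
  structure(list(
    n_second_level = check_count(n_second_level, "n_second_level"),
    alpha = check_number(alpha, "alpha", 0, 1),
    analysis_window_ms = analysis_window_ms,
    alternative = match.arg(alternative),
    seed = seed
  ), class = "stat_config")
}

#' Analysis window for a lock event
#'
#' Statistical analysis is restricted to 0--500 ms after ping onset for
#' ping-locked data and to 500--2000 ms after cue onset for cue-locked data
#' (the approximate range of maximal memory reinstatement).
#'
#' @param lock `"ping"` or `"cue"`.
#' @return `c(lo_ms, hi_ms)`.
#' @export
analysis_window <- function(lock = c("ping", "cue")) {
  switch(match.arg(lock), ping = c(0, 500), cue = c(500, 2000))
}

new_stat_result <- function(df, test, cfg) {
  structure(df, class = c("stat_result", class(tibble())),
            test = test, alpha = cfg$alpha,
            n_second_level = cfg$n_second_level)
}

restrict_windows <- function(window_times, cfg) {
  if (is.null(cfg$analysis_window_ms)) return(seq_along(window_times))
  sel <- which(window_times >= cfg$analysis_window_ms[1] &
                 window_times <= cfg$analysis_window_ms[2])
  if (length(sel) == 0L) {
    abort(sprintf("Analysis window [%g, %g] ms contains no decoding windows.",
                  cfg$analysis_window_ms[1], cfg$analysis_window_ms[2]))
  }
  sel
}

#' Two-level Monte-Carlo permutation test
#'
#' Window by window: each of `n_second_level` draws samples (with
#' replacement) one first-level shuffled-label decoding value per participant
#' and averages them, building the null distribution of the group-mean
#' decodability. The p-value uses the add-one convention,
#' `p = (1 + #extreme) / (n + 1)`, right-sided by default (empirical group
#' mean above the null). P-values are then Benjamini--Yekutieli adjusted
#' across the tested windows.
#'
#' @param empirical Participant x window matrix of empirical decoding values
#'   (e.g. from [timecourse_matrix()]).
#' @param first_level Participant x permutation x window array of first-level
#'   shuffled decoding values.
#' @param cfg A [stat_config()].
#' @param window_times Window centre times (ms); taken from the
#'   `window_times` attribute of `empirical` if absent.
#' @return A `stat_result` tibble: `window_time_ms`, `observed` (group mean),
#'   `null_mean`, `null_sd`, `p_raw`, `p_fdr`, `significant`.
#' @export
two_level_permutation <- function(empirical, first_level,
                                  cfg = stat_config(), window_times = NULL) {
  window_times <- window_times %||% attr(empirical, "window_times")
  if (is.null(window_times)) {
    abort("Provide `window_times` (or a matrix carrying the attribute).")
  }
  if (length(dim(first_level)) != 3L) {
    abort("`first_level` must be a participant x permutation x window array.")
  }
  n_p <- nrow(empirical)
  if (dim(first_level)[1] != n_p) {
    abort("`empirical` and `first_level` disagree on the number of participants.")
  }
  if (dim(first_level)[2] < 1L) {
    abort("Need at least one first-level permutation per participant.")
  }
  sel <- restrict_windows(window_times, cfg)
  n2 <- cfg$n_second_level
  k <- dim(first_level)[2]
  res <- with_seed(substream_seed(cfg$seed, "twolevel"), {
    purrr::map_dfr(sel, function(w) {
      fl <- first_level[, , w, drop = FALSE]
      dim(fl) <- c(n_p, k)
      draws <- matrix(fl[cbind(rep(seq_len(n_p), n2),
                               sample.int(k, n2 * n_p, replace = TRUE))],
                      n_p, n2)
      null_means <- colMeans(draws)
      obs <- mean(empirical[, w])
      n_extreme <- switch(cfg$alternative,
        greater = sum(null_means >= obs),
        less = sum(null_means <= obs),
        two.sided = min(2 * min(sum(null_means >= obs),
                                sum(null_means <= obs)), n2)
      )
      tibble(window_time_ms = window_times[w], observed = obs,
             null_mean = mean(null_means), null_sd = sd(null_means),
             p_raw = add_one_p(n_extreme, n2))
    })
  })
  res$p_fdr <- fdr_dependent(res$p_raw)
  res$significant <- res$p_fdr < cfg$alpha
  new_stat_result(res, "two_level_permutation", cfg)
}

#' Paired Wilcoxon signed-rank contrast per window
#'
#' Compares two paired sets of per-participant values window by window with
#' the Wilcoxon signed-rank test (exact when feasible at n <= 25, normal
#' approximation with continuity correction otherwise), then
#' Benjamini--Yekutieli adjusts across windows. Windows where every paired
#' difference is zero get p = 1 with a warning.
#'
#' @param a,b Participant x window matrices (paired by row).
#' @param cfg A [stat_config()]; `alternative = "greater"` tests a > b.
#' @param window_times Window centre times (ms).
#' @return A `stat_result` tibble with `statistic` (signed-rank V),
#'   `median_diff`, `p_raw`, `p_fdr`, `significant`.
#' @export
wilcoxon_contrast <- function(a, b, cfg = stat_config(), window_times = NULL) {
  window_times <- window_times %||% attr(a, "window_times")
  if (is.null(window_times)) abort("Provide `window_times`.")
  if (!all(dim(a) == dim(b))) abort("`a` and `b` must have identical dimensions.")
  if (nrow(a) < 5L) abort("Wilcoxon contrast needs at least 5 participants.")
  sel <- restrict_windows(window_times, cfg)
  res <- purrr::map_dfr(sel, function(w) {
    d <- a[, w] - b[, w]
    if (all(d == 0)) {
      warn(sprintf("All paired differences are zero at window %g ms; p = 1.",
                   window_times[w]))
      return(tibble(window_time_ms = window_times[w], statistic = NA_real_,
                    median_diff = 0, p_raw = 1))
    }
    exact <- length(d) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
      wilcox.test(a[, w], b[, w], paired = TRUE,
                  alternative = cfg$alternative, exact = exact,
                  correct = TRUE)
    )
    tibble(window_time_ms = window_times[w],
           statistic = unname(wt$statistic), median_diff = median(d),
           p_raw = wt$p.value)
  })
  res$p_fdr <- fdr_dependent(res$p_raw)
  res$significant <- res$p_fdr < cfg$alpha
  new_stat_result(res, "wilcoxon_contrast", cfg)
}

#' FDR adjustment for dependent tests (Benjamini--Yekutieli)
#'
#' Step-up false-discovery-rate adjustment with the harmonic-sum correction
#' `c(m) = sum_{i=1}^m 1/i`, valid under arbitrary dependence between the
#' tests (decoding windows are strongly autocorrelated in time). Adjusted
#' values are clipped at 1; the adjustment is idempotent on its own output.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_dependent <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BY")
}

#' Trial-count / class-count p-value simulation
#'
#' Simulates, for every combination of trial count and class count, replicate
#' null-or-effect datasets with the package's own generator, runs the full
#' feature + decoding + two-level permutation pipeline on each, and tabulates
#' the median group p-value and the spread (SD) of the second-level null
#' distribution. With an effect present, more trials (and classes) shrink the
#' shuffled distribution and drive p-values down; without an effect p-values
#' stay near 0.5 regardless of scale.
#'
#' @param trial_grid Trial counts per dataset (e.g. `c(40, 120, 240)`).
#' @param class_grid Class counts (default 2).
#' @param effect `"present"` or `"absent"`.
#' @param n_participants Participants per simulated dataset.
#' @param n_replicates Replicate datasets per grid cell.
#' @param effect_uv Pattern amplitude when the effect is present.
#' @param n_channels,epoch_ms,sfreq Reduced-scale simulation geometry.
#' @param dec_cfg A [decoder_config()] (use reduced shuffles/repetitions).
#' @param cfg A [stat_config()] (use a reduced `n_second_level`).
#' @param seed Master seed.
#' @return A tibble: `effect`, `n_trials`, `n_classes`, `median_p`,
#'   `mean_null_sd`, `n_replicates`.
#' @export
trial_count_pvalue_simulation <- function(trial_grid, class_grid = 2,
                                          effect = c("present", "absent"),
                                          n_participants = 8,
                                          n_replicates = 11,
                                          effect_uv = 5,
                                          n_channels = 8,
                                          epoch_ms = c(0, 220), sfreq = 250,
                                          dec_cfg = decoder_config(
                                            n_repetitions = 1,
                                            n_label_shuffles = 10,
                                            shuffle_repetitions = 1),
                                          cfg = stat_config(n_second_level = 2000),
                                          seed = 1) {
  effect <- match.arg(effect)
  if (length(trial_grid) == 0L || length(class_grid) == 0L) {
    abort("`trial_grid` and `class_grid` must be non-empty.")
  }
  grid <- tidyr::expand_grid(n_trials = trial_grid, n_classes = class_grid)
  purrr::pmap_dfr(grid, function(n_trials, n_classes) {
    ps <- numeric(n_replicates)
    nsd <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rseed <- substream_seed(seed, sprintf("tc%d_%d_%d", n_trials, n_classes, r))
      d <- simulate_flat_dataset(
        n_participants = n_participants, n_trials = n_trials,
        n_classes = n_classes,
        effect_uv = if (effect == "present") effect_uv else 0,
        n_channels = n_channels, epoch_ms = epoch_ms, sfreq = sfreq,
        onset_mean_ms = mean(epoch_ms), onset_jitter_sd_ms = 20,
        dec_cfg = dec_cfg, seed = rseed
      )
      icfg <- cfg
      icfg$seed <- rseed
      st <- two_level_permutation(d$empirical, d$first_level, icfg,
                                  window_times = d$window_times)
      mid <- which.min(abs(st$window_time_ms - mean(epoch_ms)))
      ps[r] <- st$p_raw[mid]
      nsd[r] <- st$null_sd[mid]
    }
    tibble(effect = effect, n_trials = n_trials, n_classes = n_classes,
           median_p = median(ps), mean_null_sd = mean(nsd),
           n_replicates = n_replicates)
  })
}

# Reduced-scale dataset: simulate -> features -> decode (+ shuffles) for
# n_participants, returning the matrices the group statistics consume.
# Shared by the trial-count simulation, tests, and calibration studies.
#' @keywords internal
simulate_flat_dataset <- function(n_participants, n_trials, n_classes = 2,
                                  effect_uv = 0, n_channels = 16,
                                  epoch_ms = c(0, 220), sfreq = 250,
                                  onset_mean_ms = 110, onset_jitter_sd_ms = 20,
                                  response_duration_ms = 150,
                                  dec_cfg = decoder_config(n_repetitions = 1,
                                                           n_label_shuffles = 10,
                                                           shuffle_repetitions = 1),
                                  spec = window_spec(), seed = 1) {
  emp <- NULL; fl <- NULL; wt <- NULL
  classes <- paste0("class", seq_len(n_classes))
  for (i in seq_len(n_participants)) {
    pseed <- substream_seed(seed, paste0("participant", i))
    design <- tibble(
      trial_id = seq_len(n_trials), phase = "recall", block = 1L,
      trial_in_block = seq_len(n_trials), pair_id = NA_character_,
      condition = "none", is_ping = FALSE, ping_time_ms = NA_real_,
      image_id = NA_character_,
      top = rep_len(classes, n_trials),
      middle = NA_character_, bottom = NA_character_, instance = NA_integer_
    )
    cfg <- sim_config(n_channels = n_channels, sfreq = sfreq,
                      epoch_ms = epoch_ms, effect_uv = effect_uv,
                      onset_mean_ms = onset_mean_ms,
                      onset_jitter_sd_ms = onset_jitter_sd_ms,
                      response_duration_ms = response_duration_ms,
                      ping_amp_uv = 0, seed = pseed)
    ep <- simulate_epochs(design, cfg, lock = "cue")
    fs <- zscore_across_channels(gaussian_moving_average(ep, spec))
    icfg <- dec_cfg
    icfg$seed <- pseed
    dtc <- decode_timecourse(fs, fs$trials$top, icfg)
    shf <- shuffled_decode(fs, fs$trials$top, icfg)
    emp <- rbind(emp, dtc$empirical)
    fl <- abind3(fl, shf)
    wt <- dtc$window_times
  }
  list(empirical = emp, first_level = fl, window_times = wt)
}

# bind a permutation x window matrix into a participant x perm x window array
abind3 <- function(arr, m) {
  if (is.null(arr)) {
    array(m, c(1, nrow(m), ncol(m)))
  } else {
    out <- array(NA_real_, c(dim(arr)[1] + 1, dim(arr)[2], dim(arr)[3]))
    out[seq_len(dim(arr)[1]), , ] <- arr
    out[dim(out)[1], , ] <- m
    out
  }
}

#' Intertrial variance contrast between ping and no-ping trials
#'
#' For each participant and channel, computes the across-trial variance of
#' the voltage at every sample, averages it over a time window, and compares
#' ping against no-ping conditions with a paired Wilcoxon signed-rank test
#' across participants (per channel, Benjamini--Yekutieli adjusted). A
#' latency-regularizing ping (`rho` near 1 on jittered signal) reduces
#' intertrial variance in signal-carrying channels.
#'
#' @param ping_list,noping_list Lists of `eeg_epochs` (one per participant)
#'   for the two conditions.
#' @param window `c(lo, hi)` ms averaging window.
#' @param cfg A [stat_config()]; default sidedness `"less"` (ping variance
#'   below no-ping).
#' @return A tibble: `channel`, `mean_ping`, `mean_noping`, `statistic`,
#'   `p_raw`, `p_fdr`, `significant`.
#' @export
intertrial_variance_contrast <- function(ping_list, noping_list,
                                         window = c(0, 500),
                                         cfg = stat_config(alternative = "less")) {
  if (length(ping_list) != length(noping_list) || length(ping_list) == 0L) {
    abort("Need paired, non-empty lists of per-participant epochs.")
  }
  chan_var <- function(ep) {
    if (dim(ep$data)[1] < 2L) {
      abort("Each condition needs at least 2 trials per participant.")
    }
    sel <- ep$times >= window[1] & ep$times <= window[2]
    v <- apply(ep$data[, , sel, drop = FALSE], c(2, 3), var)
    rowMeans(v)
  }
  vp <- do.call(rbind, purrr::map(ping_list, chan_var))      # participant x ch
  vn <- do.call(rbind, purrr::map(noping_list, chan_var))
  channels <- ping_list[[1]]$channels
  res <- purrr::map_dfr(seq_along(channels), function(ch) {
    d <- vp[, ch] - vn[, ch]
    if (all(d == 0)) {
      return(tibble(channel = channels[ch], mean_ping = mean(vp[, ch]),
                    mean_noping = mean(vn[, ch]), statistic = NA_real_,
                    p_raw = 1))
    }
    wt <- suppressWarnings(
      wilcox.test(vp[, ch], vn[, ch], paired = TRUE,
                  alternative = cfg$alternative)
    )
    tibble(channel = channels[ch], mean_ping = mean(vp[, ch]),
           mean_noping = mean(vn[, ch]), statistic = unname(wt$statistic),
           p_raw = wt$p.value)
  })
  res$p_fdr <- fdr_dependent(res$p_raw)
  res$significant <- res$p_fdr < cfg$alpha
  res
}
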