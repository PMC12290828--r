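# Event-related potentials over posterior channels and the ping vs no-ping
# amplitude contrast.

#' Condition-average event-related potentials
#'
#' Band-pass filters every trial (zero-phase Butterworth), baseline-corrects,
#' averages across trials per condition, and additionally averages across the
#' posterior channel set for trace output.
#'
#' @param epochs An `eeg_epochs` object; conditions are read from
#'   `condition_col` in the trial metadata.
#' @param band `c(low, high)` Hz pass band (default 0.2--40).
#' @param baseline Baseline window ms (default -200..0); `NULL` to skip.
#' @param channel_set Channels averaged for the posterior trace (default
#'   [posterior_channels()], intersected with the available montage).
#' @param condition_col Metadata column defining conditions.
#' @param order Butterworth order (default 2 per pass).
#' @return An `erp_result` with `traces` (tibble: time, condition, posterior
#'   mean) and `channel_means` (condition x channel x time array).
#' @export
erp_average <- function(epochs, band = c(0.2, 40), baseline = c(-200, 0),
                        channel_set = posterior_channels(),
                        condition_col = "condition", order = 2) {
  unknown <- setdiff(channel_set, epochs$channels)
  if (length(unknown) == length(channel_set)) {
    abort(paste0("Unknown channel(s): ", paste(unknown, collapse = ", ")))
  }
  channel_set <- intersect(channel_set, epochs$channels)
  filtered <- filter_epochs(epochs, band, order)
  if (!is.null(baseline)) filtered <- baseline_correct(filtered, baseline)
  cond <- filtered$trials[[condition_col]]
  cond[is.na(cond)] <- "none"
  conds <- unique(cond)
  d <- dim(filtered$data)
  channel_means <- array(NA_real_, c(length(conds), d[2], d[3]),
                         dimnames = list(conds, filtered$channels, NULL))
  for (k in seq_along(conds)) {
    channel_means[k, , ] <-
      apply(filtered$data[cond == conds[k], , , drop = FALSE], c(2, 3), mean)
  }
  post_idx <- match(channel_set, filtered$channels)
  traces <- purrr::map_dfr(seq_along(conds), function(k) {
    tibble(time_ms = filtered$times, condition = conds[k],
           posterior_mean_uv = colMeans(channel_means[k, post_idx, ,
                                                      drop = FALSE][1, , ]))
  })
  structure(list(traces = traces, channel_means = channel_means,
                 times = filtered$times, channels = filtered$channels,
                 channel_set = channel_set, band = band),
            class = "erp_result")
}

filter_epochs <- function(epochs, band, order) {
  nyq <- epochs$sfreq / 2
  if (band[2] >= nyq) abort("Filter band reaches the Nyquist frequency.")
  bf <- signal::butter(order, band / nyq, type = "pass")
  d <- dim(epochs$data)
  flat <- t(matrix(epochs$data, d[1] * d[2], d[3]))
  filt <- apply(flat, 2, function(v) signal::filtfilt(bf, v))
  epochs$data <- array(t(filt), d)
  epochs
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result> %d conditions x %d channels x %d samples\n",
              dim(x$channel_means)[1], dim(x$channel_means)[2],
              dim(x$channel_means)[3]))
  invisible(x)
}

#' @rdname erp_average
#' @param x An `erp_result`.
#' @param ... Unused.
#' @method tidy erp_result
#' @export
tidy.erp_result <- function(x, ...) x$traces

#' Ping vs no-ping ERP amplitude contrast
#'
#' Per channel, averages each participant's mean amplitude over a post-event
#' window in ping-locked and pseudo-ping-locked data, and compares the
#' conditions with a Monte-Carlo sign-flip permutation of the per-participant
#' condition assignment (the participant is the exchangeability unit).
#' P-values use the add-one convention and are Bonferroni-corrected across
#' channels.
#'
#' @param ping_list,noping_list Lists of `eeg_epochs` per participant
#'   (ping-locked and pseudo-ping-locked), sharing a channel montage.
#' @param window `c(lo, hi)` ms averaging window after the (pseudo-)ping
#'   (default 200--400).
#' @param n_randomizations Monte-Carlo randomizations (default 1e5).
#' @param alpha Significance level after Bonferroni correction.
#' @param alternative `"greater"` (default: ping above no-ping),
#'   `"less"`, or `"two.sided"`.
#' @param seed Seed for the randomizations.
#' @return A tibble: `channel`, `mean_diff_uv`, `p_raw`, `p_bonf`,
#'   `significant`.
#' @export
ping_contrast <- function(ping_list, noping_list, window = c(200, 400),
                          n_randomizations = 1e5, alpha = 0.05,
                          alternative = c("greater", "less", "two.sided"),
                          seed = 1) {
  alternative <- match.arg(alternative)
  if (length(ping_list) != length(noping_list) || length(ping_list) == 0L) {
    abort("Need paired, non-empty per-participant epoch lists.")
  }
  if (!identical(ping_list[[1]]$channels, noping_list[[1]]$channels)) {
    abort("Ping and no-ping epochs must share the same channel set.")
  }
  channels <- ping_list[[1]]$channels
  # participant x channel matrices of window-mean amplitude
  win_mean <- function(ep) {
    sel <- ep$times >= window[1] & ep$times <= window[2]
    colMeans(apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean))
  }
  mp <- do.call(rbind, purrr::map(ping_list, win_mean))
  mn <- do.call(rbind, purrr::map(noping_list, win_mean))
  D <- mp - mn                          # participant x channel differences
  n_p <- nrow(D)
  obs <- colMeans(D)
  n_rand <- check_count(n_randomizations, "n_randomizations")
  counts_hi <- numeric(ncol(D))
  counts_lo <- numeric(ncol(D))
  with_seed(substream_seed(seed, "pingcontrast"), {
    chunk <- 20000L
    done <- 0L
    while (done < n_rand) {
      m <- min(chunk, n_rand - done)
      signs <- matrix(sample(c(-1, 1), m * n_p, replace = TRUE), m, n_p)
      null_means <- (signs %*% D) / n_p
      counts_hi <- counts_hi + colSums(null_means >=
                                         rep(obs, each = m))
      counts_lo <- counts_lo + colSums(null_means <=
                                         rep(obs, each = m))
      done <- done + m
    }
  })
  p_raw <- switch(alternative,
    greater = add_one_p(counts_hi, n_rand),
    less = add_one_p(counts_lo, n_rand),
    two.sided = pmin(1, 2 * pmin(add_one_p(counts_hi, n_rand),
                                 add_one_p(counts_lo, n_rand)))
  )
  tibble(channel = channels, mean_diff_uv = obs, p_raw = p_raw,
         p_bonf = pmin(1, length(channels) * p_raw),
         significant = pmin(1, length(channels) * p_raw) < alpha)
}
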