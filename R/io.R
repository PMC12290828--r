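# Persistence and configuration: epochs/feature containers, trial-table CSV,
# YAML configs.

EPOCHS_FIELDS <- c("data", "times", "sfreq", "channels", "lock", "trials")

#' Write / read epoched EEG
#'
#' Epochs are stored as a single RDS container with a documented layout:
#' elements `data` (trial x channel x time array, microvolts), `times` (ms),
#' `sfreq` (Hz), `channels`, `lock`, `trials` (metadata tibble), plus a
#' `format` tag. `read_epochs()` validates the layout and names any missing
#' element; the write/read round trip is exact.
#'
#' @param epochs An `eeg_epochs` object.
#' @param path File path.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` the
#'   `eeg_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  payload <- c(list(format = "pingdecode-epochs", version = 1L),
               unclass(epochs)[EPOCHS_FIELDS])
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  payload <- readRDS(path)
  missing <- setdiff(EPOCHS_FIELDS, names(payload))
  if (!is.list(payload) || length(missing) > 0L) {
    abort(paste0("Malformed epochs file: missing element(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  new_eeg_epochs(payload$data, payload$times, payload$sfreq,
                 payload$channels, payload$lock, payload$trials)
}

#' Write / read a trial design table
#'
#' @param design Trial table from [generate_design()].
#' @param path CSV file path.
#' @return `write_design()` returns `path` invisibly; `read_design()` the
#'   tibble.
#' @export
write_design <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Pipeline run configuration
#'
#' A plain, serializable description of a full pipeline run; round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_participants Number of simulated participants.
#' @param n_blocks,n_pairs_per_block,n_reps Design parameters (see
#'   [generate_design()]).
#' @param lock Lock event for the decoding analyses (`"cue"` or `"ping"`).
#' @param analyses Character subset of `c("two_level", "wilcoxon", "pod",
#'   "erp")`.
#' @param sim,window,decoder,stats Named lists of argument overrides for
#'   [sim_config()], [window_spec()], [decoder_config()] and [stat_config()].
#' @param pod_n_second_level Second-level draws for the POD test.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_participants = 5, n_blocks = 2,
                       n_pairs_per_block = 4, n_reps = 4,
                       lock = c("cue", "ping"),
                       analyses = c("two_level", "wilcoxon"),
                       sim = list(), window = list(), decoder = list(),
                       stats = list(), pod_n_second_level = 10000) {
  bad <- setdiff(analyses, c("two_level", "wilcoxon", "pod", "erp"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown analyses: ", paste(bad, collapse = ", ")))
  }
  structure(list(seed = seed, n_participants = n_participants,
                 n_blocks = n_blocks, n_pairs_per_block = n_pairs_per_block,
                 n_reps = n_reps, lock = match.arg(lock),
                 analyses = analyses, sim = sim, window = window,
                 decoder = decoder, stats = stats,
                 pod_n_second_level = pod_n_second_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
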