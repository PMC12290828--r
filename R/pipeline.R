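# End-to-end pipeline driver: simulate -> features -> decode -> statistics,
# with a manifest recording seeds, versions and outputs.

#' Run the full analysis pipeline on simulated participants
#'
#' Executes, for every simulated participant: design generation, pseudo-ping
#' assignment, epoch simulation at the configured lock, Gaussian-window +
#' z-score feature extraction, and top-level decoding of ping trials with
#' first-level shuffled-label permutations (plus a no-ping decoder). Then, as
#' selected in `config$analyses`: the two-level permutation test of ping
#' decodability, the ping vs no-ping Wilcoxon contrast, the POD test on the
#' SOA-specific decoders, and the ping-locked ERP contrast. All tables are
#' written as CSV next to a JSON manifest; identical configs yield
#' byte-identical result files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wspec <- do.call(window_spec, config$window)
  dcfg <- do.call(decoder_config, config$decoder)
  scfg <- do.call(stat_config, config$stats)
  if (is.null(scfg$analysis_window_ms)) {
    scfg$analysis_window_ms <- analysis_window(config$lock)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  participants <- purrr::map(seq_len(config$n_participants), function(i) {
    pseed <- substream_seed(config$seed, paste0("participant", i))
    design <- stage("design", {
      d <- generate_design(config$n_blocks, config$n_pairs_per_block,
                           config$n_reps, seed = pseed)
      make_pseudo_pings(d, seed = pseed)
    })
    simc <- do.call(sim_config, c(list(seed = pseed), config$sim))
    epochs <- stage("simulate", simulate_epochs(design, simc, config$lock))
    fs <- stage("features", {
      zscore_across_channels(gaussian_moving_average(epochs, wspec))
    })
    recall <- fs$trials
    dcfg_i <- dcfg
    dcfg_i$seed <- pseed
    ping_fs <- subset_features(fs, recall$is_ping)
    noping_fs <- subset_features(fs, !recall$is_ping)
    res <- stage("decode", {
      list(
        ping = decode_timecourse(ping_fs, ping_fs$trials$top, dcfg_i),
        ping_shuffled = shuffled_decode(ping_fs, ping_fs$trials$top, dcfg_i),
        noping = decode_timecourse(noping_fs, noping_fs$trials$top, dcfg_i)
      )
    })
    if ("pod" %in% config$analyses) {
      res$soa <- stage("decode", {
        purrr::map(setNames(c("early", "middle", "late"),
                            c("early", "middle", "late")), function(cond) {
          cfs <- subset_features(fs, recall$condition == cond)
          list(empirical = decode_timecourse(cfs, cfs$trials$top, dcfg_i),
               shuffled = shuffled_decode(cfs, cfs$trials$top, dcfg_i))
        })
      })
    }
    if ("erp" %in% config$analyses) {
      res$erp_epochs <- stage("simulate", {
        ep <- simulate_epochs(design, simc, lock = "ping")
        list(ping = subset_epochs(ep, ep$trials$is_ping),
             noping = subset_epochs(ep, !ep$trials$is_ping))
      })
    }
    res$design <- design
    res
  })

  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    outputs <<- c(outputs, name)
  }

  emp <- timecourse_matrix(purrr::map(participants, "ping"))
  emp_noping <- timecourse_matrix(purrr::map(participants, "noping"))
  wt <- attr(emp, "window_times")
  emit(purrr::imap_dfr(participants, function(p, i) {
    dplyr::bind_rows(
      dplyr::mutate(tidy(p$ping), participant = i, trials = "ping"),
      dplyr::mutate(tidy(p$noping), participant = i, trials = "noping")
    )
  }), "decoding_empirical.csv")

  results <- list()
  if ("two_level" %in% config$analyses) {
    fl <- NULL
    for (p in participants) fl <- abind3(fl, p$ping_shuffled)
    results$two_level <- stage("stats", {
      two_level_permutation(emp, fl, scfg, window_times = wt)
    })
    emit(as_tibble(results$two_level), "two_level.csv")
  }
  if ("wilcoxon" %in% config$analyses) {
    results$wilcoxon <- stage("stats", {
      wilcoxon_contrast(emp, emp_noping, scfg, window_times = wt)
    })
    emit(as_tibble(results$wilcoxon), "wilcoxon_ping_vs_noping.csv")
  }
  if ("pod" %in% config$analyses) {
    results$pod <- stage("pod", {
      sel <- restrict_windows(wt, scfg)
      emp_arr <- array(NA_real_, c(length(participants), 3, length(sel)))
      n_pool <- dcfg$n_label_shuffles
      shf_arr <- array(NA_real_, c(length(participants), 3, n_pool,
                                   length(sel)))
      for (i in seq_along(participants)) {
        for (ci in 1:3) {
          cond <- c("early", "middle", "late")[ci]
          emp_arr[i, ci, ] <-
            participants[[i]]$soa[[cond]]$empirical$empirical[sel]
          shf_arr[i, ci, , ] <- participants[[i]]$soa[[cond]]$shuffled[, sel]
        }
      }
      pod_test(emp_arr, shf_arr, n_second_level = config$pod_n_second_level,
               seed = substream_seed(config$seed, "pod"),
               window_times = wt[sel])
    })
    emit(tidy(results$pod), "pod_participants.csv")
    emit(glance(results$pod), "pod_summary.csv")
  }
  if ("erp" %in% config$analyses) {
    results$erp <- stage("erp", {
      ping_contrast(purrr::map(participants, ~ .x$erp_epochs$ping),
                    purrr::map(participants, ~ .x$erp_epochs$noping),
                    n_randomizations = 1e4,
                    seed = substream_seed(config$seed, "erp"))
    })
    emit(results$erp, "erp_ping_contrast.csv")
  }

  manifest <- list(
    package = "pingdecode",
    package_version = as.character(utils::packageVersion("pingdecode")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    lock = config$lock,
    n_participants = config$n_participants,
    analysis_window_ms = scfg$analysis_window_ms,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest,
                 participants = participants))
}
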