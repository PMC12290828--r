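# Trial-design generation for the ping cued-recall experiment.

CONDITIONS <- c("early", "middle", "late", "none")

#' SOA bins for ping presentation
#'
#' Pings are presented in one of three stimulus-onset-asynchrony (SOA) bins
#' after retrieval-cue onset; within each bin the ping time is uniform.
#'
#' @return A tibble with columns `condition`, `lo_ms`, `hi_ms`.
#' @export
soa_bins <- function() {
  tibble(
    condition = c("early", "middle", "late"),
    lo_ms = c(500, 833.34, 1116.68),
    hi_ms = c(833.33, 1116.67, 1500)
  )
}

#' Generate the trial design of the cued-recall ping experiment
#'
#' Builds the full encoding + recall trial table: `n_blocks` blocks, each with
#' `n_pairs_per_block` verb--image pairs encoded once and recalled `n_reps`
#' times. Each pair's repetitions are allocated one-each (or in equal
#' multiples) to the four ping conditions (early, middle, late, none), which
#' jointly enforces the 75%/25% ping/no-ping split and the balance of
#' top-level image categories within every condition. Ping times are drawn
#' uniformly within each condition's SOA bin. The recall order within a block
#' is randomized under the constraint that the same pair never occurs on two
#' consecutive recall trials.
#'
#' @param n_blocks Number of blocks (default 8).
#' @param n_pairs_per_block Verb--image pairs learned per block (default 10;
#'   must be even so object/scene categories balance).
#' @param n_reps Recall repetitions per pair (default 4; must be a multiple of
#'   the 4 conditions).
#' @param seed Integer seed; the design is a deterministic function of the
#'   arguments and the seed.
#' @param hierarchy Stimulus hierarchy tibble, normally [build_hierarchy()].
#' @return A tibble with one row per trial: `trial_id`, `phase`
#'   (encoding/recall), `block`, `trial_in_block`, `pair_id`, `condition`,
#'   `is_ping`, `ping_time_ms` (NA on no-ping and encoding rows), and the
#'   image labels `image_id`, `top`, `middle`, `bottom`, `instance`.
#' @examples
#' d <- generate_design(seed = 1)
#' sum(d$phase == "recall")   # 320
#' sum(d$phase == "encoding") # 80
#' mean(d$is_ping[d$phase == "recall"])  # 0.75
#' @export
generate_design <- function(n_blocks = 8, n_pairs_per_block = 10, n_reps = 4,
                            seed = NULL, hierarchy = build_hierarchy()) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  n_pairs_per_block <- check_count(n_pairs_per_block, "n_pairs_per_block", lower = 2)
  n_reps <- check_count(n_reps, "n_reps")
  if (n_reps %% length(CONDITIONS) != 0L) {
    abort(paste0("`n_reps` (", n_reps, ") must be a multiple of the ",
                 length(CONDITIONS), " ping conditions so each pair sees ",
                 "every condition equally often."))
  }
  if (n_pairs_per_block %% 2L != 0L) {
    abort(paste0("`n_pairs_per_block` (", n_pairs_per_block, ") must be even: ",
                 "object/scene top-level categories cannot be balanced ",
                 "within a block otherwise."))
  }
  per_top <- n_blocks * n_pairs_per_block / 2
  n_avail <- min(table(hierarchy$top))
  if (per_top > n_avail) {
    abort(sprintf(paste0("Design needs %d images per top-level category but the ",
                         "hierarchy provides only %d."), per_top, n_avail))
  }

  with_seed(if (is.null(seed)) NULL else substream_seed(seed, "design"), {
    # one image per pair, balanced at the top level, sampled without
    # replacement across the whole experiment
    imgs <- dplyr::slice_sample(dplyr::group_by(hierarchy, .data$top),
                                n = per_top)
    imgs <- dplyr::ungroup(imgs)
    pairs <- purrr::map_dfr(seq_len(n_blocks), function(b) {
      tibble(block = b, slot = seq_len(n_pairs_per_block),
             top = rep(c("object", "scene"), each = n_pairs_per_block / 2))
    })
    # assign images: for each top class, shuffle its pool and deal out
    pairs <- dplyr::group_by(pairs, .data$top)
    pairs <- dplyr::mutate(pairs, img_row = {
      idx <- which(imgs$top == .data$top[1])
      idx[sample.int(length(idx))]
    })
    pairs <- dplyr::ungroup(pairs)
    pairs <- dplyr::bind_cols(
      dplyr::select(pairs, "block", "slot"),
      imgs[pairs$img_row, ]
    )
    pairs$pair_id <- sprintf("b%02d_p%02d", pairs$block, pairs$slot)

    bins <- soa_bins()
    reps_per_cond <- n_reps / length(CONDITIONS)

    recall <- purrr::map_dfr(seq_len(n_blocks), function(b) {
      bp <- pairs[pairs$block == b, ]
      tr <- tidyr::expand_grid(pair_id = bp$pair_id,
                               condition = rep(CONDITIONS, reps_per_cond))
      tr <- order_without_repeats(tr)
      tr$block <- b
      tr$trial_in_block <- seq_len(nrow(tr))
      tr
    })
    recall$is_ping <- recall$condition != "none"
    recall <- dplyr::left_join(recall, bins, by = "condition")
    recall$ping_time_ms <- NA_real_
    recall$ping_time_ms[recall$is_ping] <-
      runif(sum(recall$is_ping), recall$lo_ms[recall$is_ping],
            recall$hi_ms[recall$is_ping])
    recall$lo_ms <- recall$hi_ms <- NULL
    recall$phase <- "recall"

    encoding <- purrr::map_dfr(seq_len(n_blocks), function(b) {
      bp <- pairs[pairs$block == b, ]
      tibble(pair_id = sample(bp$pair_id), block = b,
             trial_in_block = seq_len(nrow(bp)))
    })
    encoding$phase <- "encoding"
    encoding$condition <- NA_character_
    encoding$is_ping <- FALSE
    encoding$ping_time_ms <- NA_real_

    out <- dplyr::bind_rows(encoding, recall)
    out <- dplyr::left_join(
      out,
      dplyr::select(pairs, "pair_id", "image_id", "top", "middle",
                    "bottom", "instance"),
      by = "pair_id"
    )
    out <- dplyr::arrange(out, .data$phase, .data$block, .data$trial_in_block)
    out$trial_id <- stats::ave(seq_len(nrow(out)), out$phase, FUN = seq_along)
    dplyr::select(out, "trial_id", "phase", "block", "trial_in_block",
                  "pair_id", "condition", "is_ping", "ping_time_ms",
                  "image_id", "top", "middle", "bottom", "instance")
  })
}

# Randomize trial order so no pair_id appears on two consecutive rows.
# Rejection sampling with a repair pass; feasible whenever more than one pair
# exists and no pair exceeds half the trials.
order_without_repeats <- function(tr, max_tries = 2000) {
  n <- nrow(tr)
  for (i in seq_len(max_tries)) {
    ord <- sample.int(n)
    if (!any(tr$pair_id[ord][-1] == tr$pair_id[ord][-n])) {
      return(tr[ord, , drop = FALSE])
    }
  }
  abort("Could not order recall trials without consecutive pair repeats.")
}

#' Assign pseudo-ping times to no-ping trials
#'
#' Every no-ping recall trial receives a `pseudo_ping_time_ms` sampled with
#' replacement from the pool of that design's real ping times, providing a
#' matched time-lock for baseline (pseudo-ping-locked) analyses. Ping trials
#' are unchanged.
#'
#' @param design A trial table from [generate_design()].
#' @param seed Integer seed for the (with-replacement) sampling.
#' @return `design` with an added `pseudo_ping_time_ms` column (NA on ping and
#'   encoding rows).
#' @export
make_pseudo_pings <- function(design, seed = NULL) {
  recall <- design$phase == "recall"
  pool <- design$ping_time_ms[recall & design$is_ping]
  if (length(pool) == 0L) {
    abort("Design contains no ping trials: cannot build a pseudo-ping pool.")
  }
  none <- recall & !design$is_ping
  if (!any(none)) {
    abort("Design contains no no-ping recall trials to assign pseudo-pings to.")
  }
  design$pseudo_ping_time_ms <- NA_real_
  with_seed(if (is.null(seed)) NULL else substream_seed(seed, "pseudo_ping"), {
    design$pseudo_ping_time_ms[none] <-
      sample(pool, sum(none), replace = TRUE)
  })
  design
}
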