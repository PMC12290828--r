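# Time-resolved decoding: shrinkage-regularized LDA with stratified k-fold
# cross-validation, rank-based AUC, shuffled-label first-level permutations,
# and cross-phase generalization.

#' Decoder configuration
#'
#' @param n_folds Stratified cross-validation folds (default 5).
#' @param n_repetitions CV repetitions for the empirical decoder (default 25).
#' @param metric `"auto"` (AUC for 2 classes, accuracy otherwise), `"auc"`, or
#'   `"accuracy"`.
#' @param n_label_shuffles First-level label permutations (default 100).
#' @param shuffle_repetitions CV repetitions per label permutation (default 3).
#' @param seed Master seed; fold assignment is reseeded per repetition from it.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(n_folds = 5, n_repetitions = 25,
                           metric = c("auto", "auc", "accuracy"),
                           n_label_shuffles = 100, shuffle_repetitions = 3,
                           seed = 1) {
  n_folds <- check_count(n_folds, "n_folds", lower = 2)
  structure(list(
    n_folds = n_folds,
    n_repetitions = check_count(n_repetitions, "n_repetitions"),
    metric = match.arg(metric),
    n_label_shuffles = check_count(n_label_shuffles, "n_label_shuffles"),
    shuffle_repetitions = check_count(shuffle_repetitions, "shuffle_repetitions"),
    seed = seed
  ), class = "decoder_config")
}

# Ledoit-Wolf shrinkage of the pooled within-class covariance toward a scaled
# identity. Returns the class means and the (shrunk) covariance inverse
# applied to what prediction needs.
lda_fit <- function(X, yint, n_classes) {
  n <- nrow(X); p <- ncol(X)
  M <- matrix(0, n_classes, p)
  Xc <- X
  counts <- tabulate(yint, n_classes)
  for (c in seq_len(n_classes)) {
    rows <- yint == c
    M[c, ] <- colMeans(X[rows, , drop = FALSE])
    Xc[rows, ] <- X[rows, , drop = FALSE] -
      rep(M[c, ], each = counts[c])
  }
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  if (mu <= .Machine$double.eps) {
    warn("All features are constant in the training set; using identity covariance.")
    Sh <- diag(1, p)
  } else {
    d2 <- sum((S - diag(mu, p))^2)
    q <- rowSums((Xc %*% S) * Xc)
    b2 <- (sum(rowSums(Xc^2)^2) - 2 * sum(q) + n * sum(S^2)) / n^2
    lam <- if (d2 > .Machine$double.eps) min(1, max(0, b2 / d2)) else 1
    Sh <- (1 - lam) * S + diag(lam * mu, p)
  }
  list(M = M, Sh = Sh, prior = counts / n)
}

# binary discriminant scores (higher = class 2)
lda_score2 <- function(fit, X) {
  as.vector(X %*% solve(fit$Sh, fit$M[2, ] - fit$M[1, ]))
}

lda_predict <- function(fit, X) {
  W <- t(solve(fit$Sh, t(fit$M)))              # C x p
  sc <- X %*% t(W) - rep(0.5 * rowSums(W * fit$M) - log(fit$prior),
                         each = nrow(X))
  max.col(sc, ties.method = "first")
}

# Mann-Whitney rank AUC for scores of the positive class (yint == 2)
rank_auc <- function(scores, yint) {
  n1 <- sum(yint == 2L); n0 <- length(yint) - n1
  r <- rank(scores)
  (sum(r[yint == 2L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# stratified fold assignment: within each class, shuffled then dealt round-robin
stratified_folds <- function(yint, n_folds) {
  folds <- integer(length(yint))
  for (c in unique(yint)) {
    idx <- which(yint == c)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# one full CV pass (all folds) -> metric per window, averaged over folds
cv_pass <- function(X3, yint, n_classes, folds, n_folds, use_auc) {
  n_w <- dim(X3)[3]
  p <- dim(X3)[2]
  acc <- matrix(NA_real_, n_folds, n_w)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    yt <- yint[tr]; yh <- yint[te]
    for (w in seq_len(n_w)) {
      fit <- lda_fit(matrix(X3[tr, , w], length(tr), p), yt, n_classes)
      Xte <- matrix(X3[te, , w], length(te), p)
      acc[f, w] <- if (use_auc) {
        rank_auc(lda_score2(fit, Xte), yh)
      } else {
        mean(lda_predict(fit, Xte) == yh)
      }
    }
  }
  colMeans(acc)
}

new_decoding_timecourse <- function(window_times, empirical, metric, chance,
                                    n_classes, n_trials, classes) {
  structure(list(window_times = window_times, empirical = empirical,
                 metric = metric, chance = chance, n_classes = n_classes,
                 n_trials = n_trials, classes = classes),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %s over %d windows (%d classes, chance %.3g)\n",
              x$metric, length(x$window_times), x$n_classes, x$chance))
  cat(sprintf("  peak %.3f at %g ms\n", max(x$empirical),
              x$window_times[which.max(x$empirical)]))
  invisible(x)
}

#' @rdname decode_timecourse
#' @param x A `decoding_timecourse`.
#' @param ... Unused.
#' @method tidy decoding_timecourse
#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble(window_time_ms = x$window_times, estimate = x$empirical,
         metric = x$metric, chance = x$chance)
}

#' @rdname decode_timecourse
#' @method glance decoding_timecourse
#' @export
glance.decoding_timecourse <- function(x, ...) {
  tibble(metric = x$metric, n_windows = length(x$window_times),
         n_classes = x$n_classes, n_trials = x$n_trials, chance = x$chance,
         mean = mean(x$empirical), peak = max(x$empirical),
         peak_time_ms = x$window_times[which.max(x$empirical)])
}

prepare_labels <- function(labels, n_folds) {
  y <- factor(labels)
  if (nlevels(y) < 2L) abort("Decoding needs at least 2 classes.")
  counts <- table(y)
  if (any(counts < n_folds)) {
    abort(sprintf("Every class needs at least n_folds = %d trials (smallest has %d).",
                  n_folds, min(counts)))
  }
  y
}

#' Time-resolved cross-validated decoding
#'
#' Trains and tests a shrinkage-regularized linear discriminant on every
#' window of a feature series under stratified k-fold cross-validation
#' repeated `n_repetitions` times (fold assignment reseeded per repetition
#' from the master seed). Binary problems are scored with the rank-based
#' (Mann--Whitney) AUC, multiclass problems with accuracy against a recorded
#' chance level of `1/n_classes`.
#'
#' @param fs A `feature_series`.
#' @param labels Class label per trial (coerced to factor).
#' @param cfg A [decoder_config()].
#' @return A `decoding_timecourse`: empirical metric per window plus metadata.
#'   `tidy()` returns the per-window tibble; `glance()` a one-row summary.
#' @export
decode_timecourse <- function(fs, labels, cfg = decoder_config()) {
  y <- prepare_labels(labels, cfg$n_folds)
  yint <- as.integer(y)
  n_classes <- nlevels(y)
  use_auc <- cfg$metric == "auc" ||
    (cfg$metric %in% c("auto") && n_classes == 2L)
  if (cfg$metric == "auc" && n_classes != 2L) {
    abort("AUC is only defined for 2 classes; use accuracy.")
  }
  X3 <- fs$values
  out <- 0
  for (r in seq_len(cfg$n_repetitions)) {
    folds <- with_seed(substream_seed(cfg$seed, paste0("folds", r)),
                       stratified_folds(yint, cfg$n_folds))
    out <- out + cv_pass(X3, yint, n_classes, folds, cfg$n_folds, use_auc)
  }
  new_decoding_timecourse(
    fs$window_times, out / cfg$n_repetitions,
    metric = if (use_auc) "auc" else "accuracy",
    chance = if (use_auc) 0.5 else 1 / n_classes,
    n_classes = n_classes, n_trials = length(yint), classes = levels(y)
  )
}

#' First-level shuffled-label decoding
#'
#' Repeats the cross-validated decoding of [decode_timecourse()] with
#' `n_label_shuffles` random label permutations, each decoded with
#' `shuffle_repetitions` CV repetitions, yielding the within-participant
#' first-level null distribution of the decoding time course.
#'
#' @inheritParams decode_timecourse
#' @return A numeric matrix (permutation x window) with attributes
#'   `window_times`, `metric` and `chance`.
#' @export
shuffled_decode <- function(fs, labels, cfg = decoder_config()) {
  y <- prepare_labels(labels, cfg$n_folds)
  sub_cfg <- cfg
  sub_cfg$n_repetitions <- cfg$shuffle_repetitions
  out <- matrix(NA_real_, cfg$n_label_shuffles, length(fs$window_times))
  metric <- NULL
  for (s in seq_len(cfg$n_label_shuffles)) {
    ys <- with_seed(substream_seed(cfg$seed, paste0("labelshuffle", s)),
                    sample(y))
    sub_cfg$seed <- substream_seed(cfg$seed, paste0("shufflecv", s))
    dtc <- decode_timecourse(fs, ys, sub_cfg)
    out[s, ] <- dtc$empirical
    metric <- dtc$metric
  }
  structure(out, window_times = fs$window_times, metric = metric,
            chance = if (identical(metric, "auc")) 0.5 else
              1 / nlevels(y))
}

#' Cross-phase decoding (train on one phase, test on another)
#'
#' Trains a single shrinkage LDA on all training windows whose centres fall in
#' `train_window` (each (trial, window) sample pooled as an independent
#' training instance by default, or window-averaged with `pool = "average"`),
#' then applies it to every window of the test series. No cross-validation is
#' used: the phases are disjoint recordings.
#'
#' @param train_fs,test_fs `feature_series` objects sharing a feature space.
#' @param train_labels,test_labels Class labels per trial.
#' @param cfg A [decoder_config()].
#' @param train_window `c(lo, hi)` ms; training windows with centres inside
#'   (inclusive) are used. Default 100--1000 ms.
#' @param pool `"pool"` (default) or `"average"`.
#' @return A `decoding_timecourse` over the test windows.
#' @export
cross_decode <- function(train_fs, train_labels, test_fs, test_labels,
                         cfg = decoder_config(), train_window = c(100, 1000),
                         pool = c("pool", "average")) {
  pool <- match.arg(pool)
  if (!identical(train_fs$feature_names, test_fs$feature_names)) {
    abort("Training and test series must share the same feature space.")
  }
  sel <- which(train_fs$window_times >= train_window[1] &
                 train_fs$window_times <= train_window[2])
  if (length(sel) == 0L) {
    abort(sprintf("No training windows inside [%g, %g] ms.",
                  train_window[1], train_window[2]))
  }
  ytr <- factor(train_labels)
  yte <- factor(test_labels, levels = levels(ytr))
  if (anyNA(yte)) abort("Test labels contain classes absent from training.")
  n_classes <- nlevels(ytr)
  use_auc <- cfg$metric == "auc" ||
    (cfg$metric == "auto" && n_classes == 2L)

  n_tr <- dim(train_fs$values)[1]
  p <- dim(train_fs$values)[2]
  if (pool == "pool") {
    Xtr <- do.call(rbind, lapply(sel, function(w) {
      matrix(train_fs$values[, , w], n_tr, p)
    }))
    ytr_int <- rep(as.integer(ytr), times = length(sel))
  } else {
    Xtr <- apply(train_fs$values[, , sel, drop = FALSE], c(1, 2), mean)
    ytr_int <- as.integer(ytr)
  }
  fit <- lda_fit(Xtr, ytr_int, n_classes)
  yte_int <- as.integer(yte)
  n_te <- dim(test_fs$values)[1]
  emp <- vapply(seq_along(test_fs$window_times), function(w) {
    Xte <- matrix(test_fs$values[, , w], n_te, p)
    if (use_auc) rank_auc(lda_score2(fit, Xte), yte_int)
    else mean(lda_predict(fit, Xte) == yte_int)
  }, numeric(1))
  new_decoding_timecourse(
    test_fs$window_times, emp,
    metric = if (use_auc) "auc" else "accuracy",
    chance = if (use_auc) 0.5 else 1 / n_classes,
    n_classes = n_classes, n_trials = nrow(test_fs$trials),
    classes = levels(ytr)
  )
}

#' Select the most decodable stimulus category level
#'
#' Decodes each hierarchy level (top, middle, bottom) with a multiclass
#' shrinkage LDA (accuracy metric, per-level chance `1/n_classes`) on each
#' participant's feature series, compares empirical performance against the
#' mean of that participant's shuffled-label decoders with a per-window
#' Wilcoxon signed-rank test across participants, FDR-corrects
#' (Benjamini--Yekutieli) across windows, and selects a level. Selection rule:
#' the level with the most significant windows; ties broken by the largest
#' peak chance-normalized accuracy `(acc - chance) / (1 - chance)`; remaining
#' ties by higher (coarser) level.
#'
#' @param fs_list List of `feature_series`, one per participant, whose
#'   `$trials` metadata contains the label columns.
#' @param levels Label columns to compare (default `c("top", "middle",
#'   "bottom")`).
#' @param cfg A [decoder_config()].
#' @param stat_cfg A [stat_config()] (controls alpha, sidedness and FDR).
#' @return A list with `report` (one row per level: n_classes, chance,
#'   peak, normalized peak, n significant windows), `selected` (level name),
#'   and `per_level` (decoding, shuffled and stat details per level).
#' @export
level_selection <- function(fs_list, levels = c("top", "middle", "bottom"),
                            cfg = decoder_config(),
                            stat_cfg = stat_config()) {
  missing_lv <- setdiff(levels, names(fs_list[[1]]$trials))
  if (length(missing_lv) > 0L) {
    abort(paste0("Label column(s) missing from trial metadata: ",
                 paste(missing_lv, collapse = ", ")))
  }
  acfg <- cfg
  acfg$metric <- "accuracy"
  per_level <- purrr::map(setNames(levels, levels), function(lv) {
    emp <- NULL; shf_mean <- NULL; dtc1 <- NULL
    for (i in seq_along(fs_list)) {
      fs <- fs_list[[i]]
      icfg <- acfg
      icfg$seed <- substream_seed(acfg$seed, paste0("p", i, lv))
      dtc <- decode_timecourse(fs, fs$trials[[lv]], icfg)
      shf <- shuffled_decode(fs, fs$trials[[lv]], icfg)
      emp <- rbind(emp, dtc$empirical)
      shf_mean <- rbind(shf_mean, colMeans(shf))
      dtc1 <- dtc
    }
    stats <- wilcoxon_contrast(emp, shf_mean, cfg = stat_cfg,
                               window_times = dtc1$window_times)
    list(empirical = emp, shuffled_mean = shf_mean, stats = stats,
         n_classes = dtc1$n_classes, chance = dtc1$chance,
         window_times = dtc1$window_times)
  })
  report <- purrr::imap_dfr(per_level, function(x, lv) {
    grp <- colMeans(x$empirical)
    tibble(level = lv, n_classes = x$n_classes, chance = x$chance,
           peak_accuracy = max(grp),
           peak_above_chance = (max(grp) - x$chance) / (1 - x$chance),
           n_significant = sum(x$stats$significant))
  })
  ord <- order(-report$n_significant, -report$peak_above_chance,
               match(report$level, levels))
  list(report = report, selected = report$level[ord[1]],
       per_level = per_level)
}

#' Stack per-participant decoding time courses into a matrix
#'
#' @param x List of `decoding_timecourse` objects with identical windows.
#' @return Participant x window numeric matrix with `window_times` attribute.
#' @export
timecourse_matrix <- function(x) {
  wt <- x[[1]]$window_times
  m <- do.call(rbind, purrr::map(x, "empirical"))
  structure(m, window_times = wt)
}
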