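# Time-resolved pseudo-trial decoding of epoch sets: leave-one-split-out
# within a location set (same-location) or train on one location set and test
# on the other (cross-location), with per-time-point F-value feature
# selection, Gaussian smoothing, peak normalization and latency estimation.

#' Partition trials of each condition into pseudo-trial splits
#'
#' Random partition of every condition's trial indices into `n_splits`
#' near-equal sets (sizes differ by at most 1); averaging within each set
#' yields the pseudo-trials used for decoding.
#'
#' @param trial_indices Named list of integer vectors, one per condition.
#' @param n_splits Number of splits.
#' @param seed Integer RNG seed.
#' @return Named list (per condition) of lists of index vectors.
#' @export
make_pseudotrials <- function(trial_indices, n_splits, seed = 1L) {
  stopifnot(is.list(trial_indices), n_splits >= 1)
  set.seed(seed)
  lapply(stats::setNames(names(trial_indices), names(trial_indices)),
         function(cond) {
    idx <- trial_indices[[cond]]
    if (length(idx) < n_splits) {
      stop(sprintf("condition %s has %d trials, fewer than %d splits",
                   cond, length(idx), n_splits))
    }
    shuffled <- sample(idx)
    split(shuffled, rep_len(seq_len(n_splits), length(shuffled)))
  })
}

#' Rank features by one-way ANOVA F across condition cells
#'
#' Between/within mean-square ratio per feature, computed on training samples
#' only. A feature with zero within-group variance but distinct group means
#' gets infinite F and is ranked first (with a warning); a constant feature
#' gets F = 0 and is ranked last. Ties break by feature index.
#'
#' @param train_data Sample x feature matrix.
#' @param labels Per-sample condition labels (>= 2 conditions, each with >= 2
#'   samples).
#' @return List with `order` (feature indices, most informative first) and
#'   `f` (the F statistics in input order).
#' @export
select_features_by_f <- function(train_data, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 conditions")
  counts <- table(labels)
  if (any(counts < 2)) stop("every condition needs at least 2 samples")
  n <- nrow(train_data)
  gm <- colMeans(train_data)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    rows <- labels == g
    mg <- colMeans(train_data[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (mg - gm)^2
    ssw <- ssw + colSums((train_data[rows, , drop = FALSE] -
                            rep(mg, each = sum(rows)))^2)
  }
  df_b <- length(groups) - 1
  df_w <- n - length(groups)
  f <- (ssb / df_b) / (ssw / df_w)
  zero_w <- ssw == 0
  if (any(zero_w & ssb > 0)) {
    warning("feature(s) with zero within-group variance ranked first")
    f[zero_w & ssb > 0] <- Inf
  }
  f[zero_w & ssb == 0] <- 0
  list(order = order(f, decreasing = TRUE), f = unname(f))
}

#' Time-resolved decoding of an epoch set
#'
#' Per repeat, trials of every (condition, location set) cell are freshly
#' partitioned into pseudo-trials. At each time point the `k` most informative
#' features (training-set F values) feed a linear SVM (C = 1):
#' `same_location` pools both location sets into the split structure and
#' leaves one split out per fold; `cross_location` trains on all pseudo-trials
#' of one location set and tests on the other, averaging both directions.
#' Accuracies are averaged over folds/directions and repeats.
#'
#' @param epochs An [epoch_set()].
#' @param region Region name to decode (features are restricted to it).
#' @param target `"category"` or `"orientation"`.
#' @param scheme `"same_location"` or `"cross_location"`.
#' @param n_splits Pseudo-trial splits per condition cell.
#' @param n_repeats Number of re-partitioned repeats.
#' @param k Features selected per time point.
#' @param cost SVM regularization constant.
#' @param seed Integer RNG seed.
#' @return An object of class `decoding_timecourse` with `accuracy` per time,
#'   `times`, and metadata.
#' @export
decode_timecourse <- function(epochs, region, target = c("category", "orientation"),
                              scheme = c("same_location", "cross_location"),
                              n_splits = 8, n_repeats = 20, k = 100, cost = 1,
                              seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  target <- match.arg(target)
  scheme <- match.arg(scheme)
  if (!region %in% epochs$feature_region) {
    stop(sprintf("region %s not present in the epoch set", region))
  }
  feat_idx <- which(epochs$feature_region == region)
  n_time <- length(epochs$times)
  tt <- epochs$trial_table
  cells <- interaction(tt$category, tt$orientation, tt$location_set, sep = "|",
                       drop = FALSE)
  cell_ids <- levels(cells)
  trial_idx <- lapply(stats::setNames(cell_ids, cell_ids),
                      function(cl) which(cells == cl))
  meta <- do.call(rbind, strsplit(cell_ids, "|", fixed = TRUE))
  cell_info <- data.frame(category = meta[, 1], orientation = meta[, 2],
                          location_set = meta[, 3], stringsAsFactors = FALSE)
  X <- epochs$data[, feat_idx, , drop = FALSE]
  acc_sum <- numeric(n_time)
  for (rep_i in seq_len(n_repeats)) {
    parts <- make_pseudotrials(trial_idx, n_splits,
                               seed = seed + 1000L * (rep_i - 1L))
    ps <- pseudotrial_array(X, parts)
    acc_sum <- acc_sum + decode_pseudos(ps, cell_info, target, scheme,
                                        n_splits, k, cost)
  }
  structure(list(accuracy = acc_sum / n_repeats, times = epochs$times,
                 chance = 0.5, scheme = scheme, n_repeats = n_repeats,
                 n_splits = n_splits, k = k, half_width = NULL,
                 region = region, target = target),
            class = "decoding_timecourse")
}

# Average trials into pseudo-trials: returns list(data = pseudo x feature x
# time array, cell = cell id per pseudo, split = split id per pseudo).
pseudotrial_array <- function(X, parts) {
  n_feat <- dim(X)[2]; n_time <- dim(X)[3]
  rows <- list(); cell <- character(0); split_id <- integer(0)
  Xm <- matrix(X, nrow = dim(X)[1])  # trials x (feature*time)
  for (cl in names(parts)) {
    for (s in seq_along(parts[[cl]])) {
      idx <- parts[[cl]][[s]]
      rows[[length(rows) + 1L]] <- colMeans(Xm[idx, , drop = FALSE])
      cell <- c(cell, cl)
      split_id <- c(split_id, s)
    }
  }
  P <- do.call(rbind, rows)
  list(data = array(P, dim = c(nrow(P), n_feat, n_time)), cell = cell,
       split = split_id)
}

decode_pseudos <- function(ps, cell_info, target, scheme, n_splits, k, cost) {
  cell_map <- match(ps$cell, levels(factor(ps$cell)))
  info <- cell_info[match(ps$cell, interaction(cell_info$category,
                                               cell_info$orientation,
                                               cell_info$location_set,
                                               sep = "|")), ]
  lab <- info[[target]]
  cond4 <- paste(info$category, info$orientation)  # 4 condition cells for F
  lv <- sort(unique(lab))
  n_time <- dim(ps$data)[3]
  acc <- numeric(n_time)
  if (scheme == "same_location") {
    folds <- lapply(seq_len(n_splits), function(s) {
      list(train = which(ps$split != s), test = which(ps$split == s))
    })
  } else {
    aset <- which(info$location_set == "A")
    bset <- which(info$location_set == "B")
    folds <- list(list(train = aset, test = bset),
                  list(train = bset, test = aset))
  }
  for (ti in seq_len(n_time)) {
    Xt <- ps$data[, , ti]
    n_ok <- 0L; n_tot <- 0L
    for (fl in folds) {
      sel <- select_features_by_f(Xt[fl$train, , drop = FALSE],
                                  cond4[fl$train])
      use <- sel$order[seq_len(min(k, ncol(Xt)))]
      Xtr <- Xt[fl$train, use, drop = FALSE]
      Xte <- Xt[fl$test, use, drop = FALSE]
      mu <- colMeans(Xtr)
      Xtr <- sweep(Xtr, 2, mu)
      Xte <- sweep(Xte, 2, mu)
      fit <- fit_linear_svm(Xtr, factor(lab[fl$train], levels = lv), cost)
      pred <- svm_predict(fit, Xte, lv)
      n_ok <- n_ok + sum(pred == lab[fl$test], na.rm = TRUE)
      n_tot <- n_tot + length(fl$test)
    }
    acc[ti] <- n_ok / n_tot
  }
  acc
}

#' Gaussian smoothing of a time series
#'
#' Convolution with a Gaussian kernel whose half-width-at-half-maximum equals
#' `half_width` (sigma = half_width / sqrt(2 ln 2)), with reflected-boundary
#' padding. `half_width = 0` returns the input unchanged. `NA` values are
#' ignored via normalized convolution and stay `NA` in the output.
#'
#' @param series Numeric vector sampled at `sfreq`.
#' @param half_width Half-width-at-half-maximum in seconds.
#' @param sfreq Sampling frequency (Hz).
#' @return Smoothed series of the same length.
#' @export
gaussian_smooth <- function(series, half_width, sfreq) {
  stopifnot(half_width >= 0)
  if (half_width == 0 || length(series) < 2) return(series)
  sigma <- half_width / sqrt(2 * log(2)) * sfreq
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  if (anyNA(series)) {
    ok <- !is.na(series)
    filled <- ifelse(ok, series, 0)
    num <- reflect_convolve(filled, k)
    den <- reflect_convolve(as.numeric(ok), k)
    out <- num / den
    out[!ok] <- NA
    return(out)
  }
  reflect_convolve(series, k)
}

#' Smooth a decoding time course
#'
#' @param tc A `decoding_timecourse`.
#' @param half_width Half-width-at-half-maximum in seconds.
#' @return The time course with smoothed accuracies and recorded half-width.
#' @export
smooth_timecourse <- function(tc, half_width = 0.1) {
  sfreq <- 1 / stats::median(diff(tc$times))
  tc$accuracy <- gaussian_smooth(tc$accuracy, half_width, sfreq)
  tc$half_width <- half_width
  tc
}

#' Normalize a decoding time course to its post-stimulus peak
#'
#' Returns `(accuracy - chance) / (peak - chance)` with the peak taken over
#' t > 0; pre-stimulus accuracy is noise, so it never defines the peak.
#'
#' @param tc A `decoding_timecourse`.
#' @return Unitless series with maximum 1 over t > 0.
#' @export
normalize_to_peak <- function(tc) {
  post <- tc$times > 0
  peak <- max(tc$accuracy[post])
  if (!is.finite(peak) || peak <= tc$chance) stop("no above-chance peak")
  (tc$accuracy - tc$chance) / (peak - tc$chance)
}

#' Latency to a fraction of peak decoding performance
#'
#' Threshold = chance + fraction x (peak - chance), peak over t > 0. Returns
#' the first time at or after stimulus onset at which the (smoothed) accuracy
#' crosses the threshold, linearly interpolated between samples.
#'
#' @param tc A smoothed `decoding_timecourse`.
#' @param fraction Fraction of the above-chance peak (default 0.75).
#' @return List of class `latency_estimate`: `time`, `fraction`,
#'   `peak_value`, `peak_time`, `valid`.
#' @export
latency_to_fraction <- function(tc, fraction = 0.75) {
  post <- which(tc$times > 0)
  peak <- max(tc$accuracy[post])
  out <- list(time = NA_real_, fraction = fraction, peak_value = peak,
              peak_time = tc$times[post[which.max(tc$accuracy[post])]],
              valid = FALSE)
  class(out) <- "latency_estimate"
  if (!is.finite(peak) || peak <= tc$chance) return(out)
  thr <- tc$chance + fraction * (peak - tc$chance)
  at <- which(tc$times >= 0)
  acc <- tc$accuracy[at]
  hit <- which(acc >= thr)
  if (!length(hit)) return(out)
  i <- hit[1]
  if (i == 1) {
    out$time <- tc$times[at[1]]
  } else {
    t0 <- tc$times[at[i - 1]]; t1 <- tc$times[at[i]]
    a0 <- acc[i - 1]; a1 <- acc[i]
    out$time <- t0 + (thr - a0) / (a1 - a0) * (t1 - t0)
  }
  out$valid <- TRUE
  out
}
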