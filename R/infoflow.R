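# Representational strength (signed hyperplane distance per trial and time
# point) and conditional Granger causality between regions, with the
# pre-stimulus baseline used for group inference.

#' Per-trial hyperplane-distance strength time course
#'
#' At each time point, classifiers are trained exactly as in
#' [decode_timecourse()] (same scheme and F-value feature selection), but
#' every raw trial of the evaluation set is scored with its geometric margin:
#' `distance = decision value / |w|`, signed positive toward the trial's true
#' class. With the cross-location scheme each trial is scored by the
#' hyperplane trained on pseudo-trials of the opposite location set (this
#' isolates the location-invariant feedback component in retinotopic cortex);
#' with the same-location scheme each trial is scored by the fold in which its
#' split was held out.
#'
#' @inheritParams decode_timecourse
#' @return An object of class `strength_timecourse` with `distance` (trial x
#'   time), `times`, and metadata.
#' @export
strength_timecourse <- function(epochs, region,
                                target = c("category", "orientation"),
                                scheme = c("cross_location", "same_location"),
                                n_splits = 8, k = 100, cost = 1, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  target <- match.arg(target)
  scheme <- match.arg(scheme)
  feat_idx <- which(epochs$feature_region == region)
  if (!length(feat_idx)) stop(sprintf("region %s not present", region))
  tt <- epochs$trial_table
  n_trials <- nrow(tt)
  n_time <- length(epochs$times)
  cells <- interaction(tt$category, tt$orientation, tt$location_set, sep = "|",
                       drop = FALSE)
  trial_idx <- lapply(stats::setNames(levels(cells), levels(cells)),
                      function(cl) which(cells == cl))
  parts <- make_pseudotrials(trial_idx, n_splits, seed = seed)
  X <- epochs$data[, feat_idx, , drop = FALSE]
  ps <- pseudotrial_array(X, parts)
  meta <- do.call(rbind, strsplit(ps$cell, "|", fixed = TRUE))
  ps_lab <- meta[, match(target, FEATURES)]
  ps_loc <- meta[, 3]
  ps_cond4 <- paste(meta[, 1], meta[, 2])
  lab_trial <- as.character(tt[[target]])
  lv <- sort(unique(lab_trial))
  # Which split each trial belongs to (for same-location held-out scoring).
  trial_split <- integer(n_trials)
  for (cl in names(parts)) {
    for (s in seq_along(parts[[cl]])) trial_split[parts[[cl]][[s]]] <- s
  }
  distance <- matrix(NA_real_, n_trials, n_time)
  if (scheme == "cross_location") {
    eval_sets <- lapply(c(A = "A", B = "B"), function(l) {
      list(train_ps = which(ps_loc != l), eval_trials = which(tt$location_set == l))
    })
  } else {
    eval_sets <- lapply(seq_len(n_splits), function(s) {
      list(train_ps = which(ps$split != s), eval_trials = which(trial_split == s))
    })
  }
  for (ti in seq_len(n_time)) {
    Xt_ps <- ps$data[, , ti]
    Xt_tr <- X[, , ti]
    for (es in eval_sets) {
      sel <- select_features_by_f(Xt_ps[es$train_ps, , drop = FALSE],
                                  ps_cond4[es$train_ps])
      use <- sel$order[seq_len(min(k, ncol(Xt_ps)))]
      Xtr <- Xt_ps[es$train_ps, use, drop = FALSE]
      mu <- colMeans(Xtr)
      fit <- fit_linear_svm(sweep(Xtr, 2, mu),
                            factor(ps_lab[es$train_ps], levels = lv), cost)
      Xev <- sweep(Xt_tr[es$eval_trials, use, drop = FALSE], 2, mu)
      f <- svm_decision(fit, Xev)
      sgn <- ifelse(lab_trial[es$eval_trials] == fit$positive_class, 1, -1)
      distance[es$eval_trials, ti] <- sgn * f / fit$w_norm
    }
  }
  structure(list(distance = distance, times = epochs$times, region = region,
                 target = target, scheme = scheme, normalized = FALSE),
            class = "strength_timecourse")
}

#' Z-score a strength time course across trials
#'
#' Per time point, subtracts the mean and divides by the SD across trials.
#'
#' @param st A `strength_timecourse`.
#' @return The normalized time course (`normalized = TRUE`).
#' @export
normalize_strength <- function(st) {
  stopifnot(inherits(st, "strength_timecourse"))
  if (nrow(st$distance) < 3) stop("need at least 3 trials to normalize")
  mu <- colMeans(st$distance)
  sd_ <- apply(st$distance, 2, stats::sd)
  bad <- which(sd_ == 0)
  if (length(bad)) {
    stop(sprintf("zero SD across trials at time %.3f s", st$times[bad[1]]))
  }
  st$distance <- sweep(sweep(st$distance, 2, mu), 2, sd_, "/")
  st$normalized <- TRUE
  st
}

#' Conditional Granger causality between strength time courses
#'
#' For each evaluation time t, regression samples are pooled over trials and
#' the window's time points within `(t - window, t]`. The full model predicts
#' the target series from `order` lags of itself, of the source, and of every
#' other (conditioning) region, plus an intercept, by ordinary least squares;
#' the reduced model omits the source lags. The Granger influence is
#' `gc(t) = ln(U_reduced / U_full)` where U is the residual mean square, so
#' `gc >= 0` always holds for the nested fits.
#'
#' @param strengths Named list of normalized `strength_timecourse` objects
#'   (same trials and times); all regions beyond `source` and `target` enter
#'   as conditioning regressors.
#' @param source,target Region names in `strengths`.
#' @param window Sliding window length in seconds.
#' @param order Model order (number of lags).
#' @return An object of class `gc_timecourse` with `gc`, `u_full`,
#'   `u_reduced`, evaluation `times`, `lag_times`, `baseline` (mean gc over
#'   evaluation times in `(-0.2 + window, 0]`, `NA` when that interval is not
#'   covered), and metadata.
#' @export
conditional_granger <- function(strengths, source, target, window = 0.15,
                                order = 5) {
  stopifnot(is.list(strengths), source %in% names(strengths),
            target %in% names(strengths))
  for (st in strengths) {
    stopifnot(inherits(st, "strength_timecourse"))
    if (!isTRUE(st$normalized)) stop("all strength time courses must be normalized")
  }
  times <- strengths[[target]]$times
  for (st in strengths) stopifnot(identical(st$times, times),
                                  nrow(st$distance) == nrow(strengths[[target]]$distance))
  sfreq <- 1 / stats::median(diff(times))
  if (window < order / sfreq) stop("`window` must cover at least `order` samples")
  w_samp <- as.integer(round(window * sfreq))
  conditioning <- setdiff(names(strengths), c(source, target))
  region_order <- c(target, source, conditioning)
  mats <- lapply(strengths[region_order], function(s) s$distance)
  n_time <- length(times)
  eval_idx <- which(seq_len(n_time) >= w_samp + order)
  gc <- u_full <- u_red <- rep(NA_real_, length(eval_idx))
  src_cols_start <- 1L + order  # after intercept handled separately
  for (i in seq_along(eval_idx)) {
    ti <- eval_idx[i]
    J <- (ti - w_samp + 1L):ti
    y <- as.vector(mats[[1]][, J, drop = FALSE])
    Xlist <- vector("list", length(mats) * order)
    pos <- 0L
    for (r in seq_along(mats)) {
      for (l in seq_len(order)) {
        pos <- pos + 1L
        Xlist[[pos]] <- as.vector(mats[[r]][, J - l, drop = FALSE])
      }
    }
    Xfull <- cbind(1, do.call(cbind, Xlist))
    keep_red <- setdiff(seq_len(ncol(Xfull)), 1L + src_cols_start:(src_cols_start + order - 1L))
    u_full[i] <- ols_rms(Xfull, y)
    u_red[i] <- ols_rms(Xfull[, keep_red, drop = FALSE], y)
    gc[i] <- log(u_red[i] / u_full[i])
  }
  eval_times <- times[eval_idx]
  base_idx <- eval_times > (-0.2 + window) & eval_times <= 0
  baseline <- if (any(base_idx)) mean(gc[base_idx]) else NA_real_
  structure(list(gc = gc, u_full = u_full, u_reduced = u_red,
                 times = eval_times, source = source, target = target,
                 conditioning = conditioning, window = window, order = order,
                 lag_times = seq_len(order) / sfreq, baseline = baseline,
                 baseline_times = eval_times[base_idx], smoothed = FALSE),
            class = "gc_timecourse")
}

# Residual mean square of an OLS fit, with a tiny ridge fallback when the
# design is singular.
ols_rms <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    warning("singular regression design; using ridge fallback (penalty 1e-8)")
    XtX <- crossprod(X) + diag(1e-8, ncol(X))
    beta <- solve(XtX, crossprod(X, y))
    res <- y - drop(X %*% beta)
    return(mean(res^2))
  }
  mean(fit$residuals^2)
}

#' Smooth a Granger-causality time course (for reporting only)
#'
#' @param gc A `gc_timecourse`.
#' @param half_width Half-width-at-half-maximum in seconds (default 0.05).
#' @return The smoothed time course; inference should use the unsmoothed one.
#' @export
smooth_gc <- function(gc, half_width = 0.05) {
  sfreq <- 1 / stats::median(diff(gc$times))
  gc$gc <- gaussian_smooth(gc$gc, half_width, sfreq)
  gc$smoothed <- TRUE
  gc
}

#' Group-level Granger baseline correction, cluster inference, and onset
#'
#' Per subject, the pre-stimulus baseline (mean gc over evaluation times in
#' `(-0.2 + window, 0]`) is subtracted from the gc series; the resulting
#' subject x time effect matrix over post-stimulus times enters a one-tailed
#' cluster-based sign-flip permutation test. The onset is the start time of
#' the earliest significant cluster, or `NA` when none is significant.
#'
#' @param gcs List of `gc_timecourse` objects, one per subject (>= 5), on a
#'   common evaluation time axis.
#' @param n_perm Number of sign-flip permutations.
#' @param cluster_forming_p Per-time-point threshold forming clusters.
#' @param corrected_p Corrected cluster significance threshold.
#' @param seed Integer RNG seed for the permutations.
#' @return List with `baselines`, `effects` (subject x time), `times`,
#'   `clusters` (a [cluster_permutation()] result) and `onset` (seconds or
#'   `NA`).
#' @export
gc_baseline_and_onset <- function(gcs, n_perm = 2000,
                                  cluster_forming_p = 0.01,
                                  corrected_p = 0.01, seed = 1L) {
  stopifnot(length(gcs) >= 5)
  times <- gcs[[1]]$times
  for (g in gcs) stopifnot(inherits(g, "gc_timecourse"),
                           identical(g$times, times))
  baselines <- vapply(gcs, function(g) g$baseline, numeric(1))
  if (anyNA(baselines)) stop("baseline window is empty for at least one subject")
  post <- times > 0
  effects <- t(vapply(seq_along(gcs),
                      function(i) gcs[[i]]$gc[post] - baselines[i],
                      numeric(sum(post))))
  cl <- cluster_permutation(effects, null_value = 0, n_perm = n_perm,
                            cluster_forming_p = cluster_forming_p,
                            corrected_p = corrected_p, tail = "one",
                            seed = seed, times = times[post])
  sig <- cl$clusters[cl$clusters$significant, , drop = FALSE]
  onset <- if (nrow(sig)) min(sig$t_start) else NA_real_
  list(baselines = baselines, effects = effects, times = times[post],
       clusters = cl, onset = onset)
}
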