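# Trial-wise correlation between representational strength and reaction time,
# with condition-wise exclusion rules.

#' Correlate representational strength with reaction time
#'
#' Per condition (category x orientation, locations pooled): only correct
#' trials are used; trials with reaction time beyond mean +/- 2 SD of that
#' condition's correct trials are excluded; at each time point, trials that
#' are misclassified (negative distance) with high magnitude (|distance|
#' beyond 2 SD of that time point's distances within the condition) are
#' additionally excluded. The Pearson correlation between distance and
#' reaction time is computed per condition and time point, reported as
#' `-r` so that positive values mean better representation relates to faster
#' responses, averaged across the four conditions, and Gaussian-smoothed.
#'
#' @param st A `strength_timecourse` (cross-location scheme isolates the
#'   feedback component in retinotopic cortex).
#' @param trial_table Data frame aligned with `st$distance` rows, with
#'   `category`, `orientation`, `rt`, `correct`.
#' @param half_width Smoothing half-width-at-half-maximum in seconds.
#' @param min_trials Minimum usable trials per time point; below it the
#'   correlation is set to `NA` for that condition and time.
#' @return Object of class `behavior_corr_timecourse` with `r` (smoothed),
#'   `r_raw`, `per_condition` (condition x time), `n_used`, `times`,
#'   `half_width`.
#' @export
behavior_correlation <- function(st, trial_table, half_width = 0.1,
                                 min_trials = 5) {
  stopifnot(inherits(st, "strength_timecourse"),
            nrow(trial_table) == nrow(st$distance),
            all(c("category", "orientation", "rt", "correct") %in%
                  names(trial_table)))
  n_time <- ncol(st$distance)
  conds <- interaction(trial_table$category, trial_table$orientation,
                       drop = TRUE)
  cond_levels <- levels(conds)
  per_cond <- matrix(NA_real_, length(cond_levels), n_time,
                     dimnames = list(cond_levels, NULL))
  n_used <- matrix(0L, length(cond_levels), n_time)
  for (ci in seq_along(cond_levels)) {
    rows <- which(conds == cond_levels[ci] & trial_table$correct &
                    !is.na(trial_table$rt))
    if (length(rows) < 3) next
    rt <- trial_table$rt[rows]
    keep_rt <- abs(rt - mean(rt)) <= 2 * stats::sd(rt)
    rows <- rows[keep_rt]
    rt <- rt[keep_rt]
    D <- st$distance[rows, , drop = FALSE]
    sd_t <- apply(D, 2, stats::sd)
    for (ti in seq_len(n_time)) {
      d <- D[, ti]
      drop_i <- d < 0 & abs(d) > 2 * sd_t[ti]
      use <- !drop_i
      n_used[ci, ti] <- sum(use)
      if (sum(use) < min_trials || stats::sd(d[use]) == 0 ||
          stats::sd(rt[use]) == 0) next
      per_cond[ci, ti] <- -stats::cor(d[use], rt[use])
    }
  }
  r_raw <- colMeans(per_cond, na.rm = TRUE)
  r_raw[colSums(!is.na(per_cond)) == 0] <- NA
  sfreq <- 1 / stats::median(diff(st$times))
  r <- gaussian_smooth(r_raw, half_width, sfreq)
  structure(list(r = r, r_raw = r_raw, per_condition = per_cond,
                 n_used = n_used, times = st$times, half_width = half_width,
                 region = st$region, target = st$target),
            class = "behavior_corr_timecourse")
}
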