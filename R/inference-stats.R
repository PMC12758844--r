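# Group-level significance machinery: one-sample t tests, Benjamini-Hochberg
# FDR with an explicit family size, and cluster-based sign-flip permutation
# over time.

#' One-sample t test against a reference value
#'
#' @param values Per-subject values (n >= 3).
#' @param mu Reference value (chance level, baseline, or zero).
#' @param tail `"one"` (greater than `mu`) or `"two"`.
#' @return Object of class `test_result` with `t`, `df`, `p`, `tail`.
#' @export
one_sample_t <- function(values, mu = 0, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("zero variance sample")
  ht <- stats::t.test(values, mu = mu,
                      alternative = if (tail == "one") "greater" else "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, tail = tail, estimate = unname(ht$estimate)),
            class = "test_result")
}

#' Benjamini-Hochberg FDR correction with an explicit family size
#'
#' Step-up procedure with family size `m`, which may exceed the number of
#' p-values supplied (e.g. correcting a 12-test subset against a stated
#' 24-test family). Larger `m` never yields smaller q-values.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param m Total number of tests in the family (default `length(pvals)`).
#' @param alpha Rejection threshold on q.
#' @return List with `q` (adjusted values) and `reject` (logical at
#'   `q < alpha`).
#' @export
fdr_bh <- function(pvals, m = length(pvals), alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= length(pvals))
  q <- stats::p.adjust(pvals, method = "BH", n = m)
  list(q = q, reject = q < alpha)
}

#' Cluster-based sign-flip permutation test over time
#'
#' Per time point, a one-sample t across subjects tests the effect against
#' zero (callers subtract `null_value` implicitly by passing effects already
#' relative to chance/baseline, or explicitly via `null_value`). Clusters are
#' maximal runs of time points passing `cluster_forming_p` at the stated
#' tail; the cluster mass is the sum of t-values over the run. The null
#' distribution is the maximum cluster mass obtained when each subject's
#' whole time course is multiplied by an independent random sign; cluster
#' p-values use the +1 correction, `p = (1 + #null >= mass) / (1 + n_perm)`.
#'
#' @param subject_courses Subject x time effect matrix (>= 5 subjects).
#' @param null_value Value subtracted from every entry before testing.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param cluster_forming_p Per-time-point p threshold forming clusters.
#' @param corrected_p Cluster-level significance threshold.
#' @param tail `"one"` (positive effects) or `"two"`.
#' @param seed Integer RNG seed.
#' @param times Optional time axis (seconds) labeling the columns.
#' @return Object of class `cluster_result`: `clusters` data frame
#'   (`t_start`, `t_end`, `i_start`, `i_end`, `mass`, `p_corrected`,
#'   `significant`), the per-time `t` values, and the test parameters.
#' @export
cluster_permutation <- function(subject_courses, null_value = 0,
                                n_perm = 50000, cluster_forming_p = 0.01,
                                corrected_p = 0.01, tail = c("one", "two"),
                                seed = 1L, times = NULL) {
  tail <- match.arg(tail)
  E <- as.matrix(subject_courses) - null_value
  n_subj <- nrow(E)
  n_time <- ncol(E)
  if (n_subj < 5) stop("need at least 5 subjects")
  if (n_perm < 100) stop("insufficient permutations (need >= 100)")
  if (is.null(times)) times <- seq_len(n_time)
  tvals <- col_t(E)
  df <- n_subj - 1
  crit <- if (tail == "one") stats::qt(1 - cluster_forming_p, df) else
    stats::qt(1 - cluster_forming_p / 2, df)
  observed <- find_clusters(tvals, crit, tail)
  set.seed(seed)
  null_max <- numeric(n_perm)
  flips <- matrix(sample(c(-1, 1), n_subj * n_perm, replace = TRUE),
                  n_subj, n_perm)
  # Column t statistics for all permutations at once: the flipped second
  # moment is unchanged, so only the mean depends on the flips.
  m2 <- colMeans(E^2)
  P <- crossprod(E, flips) / n_subj           # time x perm means
  for (p in seq_len(n_perm)) {
    mu <- P[, p]
    s <- sqrt(pmax(m2 - mu^2, 0) * n_subj / (n_subj - 1))
    tp <- mu / (s / sqrt(n_subj))
    tp[s == 0] <- 0
    cl <- find_clusters(tp, crit, tail)
    null_max[p] <- if (nrow(cl)) max(abs(cl$mass)) else 0
  }
  if (nrow(observed)) {
    observed$p_corrected <- vapply(observed$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (1 + n_perm)
    }, numeric(1))
    observed$significant <- observed$p_corrected < corrected_p
    observed$t_start <- times[observed$i_start]
    observed$t_end <- times[observed$i_end]
  } else {
    observed$p_corrected <- numeric(0)
    observed$significant <- logical(0)
    observed$t_start <- numeric(0)
    observed$t_end <- numeric(0)
  }
  structure(list(clusters = observed[, c("t_start", "t_end", "i_start",
                                         "i_end", "mass", "p_corrected",
                                         "significant")],
                 t = tvals, times = times, df = df,
                 cluster_forming_p = cluster_forming_p,
                 corrected_p = corrected_p, n_permutations = n_perm,
                 tail = tail, seed = seed),
            class = "cluster_result")
}

col_t <- function(E) {
  n <- nrow(E)
  mu <- colMeans(E)
  s <- sqrt(colSums((E - rep(mu, each = n))^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  t[s == 0] <- 0
  t
}

# Maximal runs of supra-threshold time points. One-tailed: t > crit (positive
# side). Two-tailed: |t| > crit, split wherever the sign changes.
find_clusters <- function(tvals, crit, tail) {
  supra <- if (tail == "one") tvals > crit else abs(tvals) > crit
  if (!any(supra)) {
    return(data.frame(i_start = integer(0), i_end = integer(0),
                      mass = numeric(0)))
  }
  grp <- if (tail == "one") supra else supra * sign(tvals)
  r <- rle(as.vector(grp))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.frame(i_start = starts[keep], i_end = ends[keep],
             mass = mapply(function(a, b) sum(tvals[a:b]),
                           starts[keep], ends[keep]))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s-tailed, %d permutations, forming p<%g, corrected p<%g\n",
              x$tail, x$n_permutations, x$cluster_forming_p, x$corrected_p))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}
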