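# Laminar fMRI analysis: vasculature cleanup (two-Gaussian mixtures on betas
# and detrended EPI), dominant-fraction layer assignment, t-value voxel
# selection, and leave-one-run-out linear-SVM decoding of block-wise
# responses.

#' Remove the spatial trend from mean EPI intensity
#'
#' Ordinary least-squares fit of intensity on an intercept and the three
#' spatial coordinates; returns the residuals. Veins appear as dark outliers
#' only after the smooth spatial intensity profile of the ROI is removed.
#'
#' @param mean_epi Per-voxel mean EPI intensity.
#' @param coords Voxel x 3 coordinate matrix.
#' @return Per-voxel residual intensity (sums to ~0).
#' @export
detrend_epi <- function(mean_epi, coords) {
  coords <- as.matrix(coords)
  stopifnot(length(mean_epi) == nrow(coords))
  if (length(mean_epi) < 8) stop("detrend_epi needs at least 8 voxels")
  X <- cbind(1, coords)
  fit <- stats::lm.fit(X, mean_epi)
  if (fit$rank < ncol(X)) {
    warning("detrend_epi: rank-deficient coordinate design; mean-centering only")
    return(mean_epi - mean(mean_epi))
  }
  unname(fit$residuals)
}

#' Fit a two-component Gaussian mixture to a 1-D sample
#'
#' Expectation-maximization with a median-split initialization, a 1e-6
#' log-likelihood tolerance and at most 500 iterations. Components are
#' reported in ascending order of mean. `separation` is the absolute mean
#' difference over the weight-pooled SD and gates vasculature exclusion
#' downstream: a two-component fit on unimodal data splits arbitrarily, so
#' exclusion is only trusted when the fit is clearly bimodal.
#'
#' @param values Numeric vector, at least 20 finite values.
#' @return An object of class `mixture_fit` with `means`, `sds`, `weights`,
#'   `responsibilities` (n x 2), `separation`, `converged`, `n_iter`,
#'   `loglik`.
#' @export
fit_two_gaussian_mixture <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) stop("fit_two_gaussian_mixture needs at least 20 finite values")
  if (stats::var(values) == 0) stop("degenerate sample: zero variance")
  med <- stats::median(values)
  lo <- values <= med
  sd_floor <- 1e-6 * stats::sd(values)
  mu <- c(mean(values[lo]), mean(values[!lo]))
  sdv <- pmax(c(stats::sd(values[lo]), stats::sd(values[!lo])), sd_floor,
              na.rm = TRUE)
  sdv[is.na(sdv)] <- sd_floor
  w <- c(mean(lo), 1 - mean(lo))
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0.5, n, 2)
  for (iter in seq_len(500L)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sdv[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sdv[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    resp <- cbind(d1 / tot, d2 / tot)
    ll <- sum(log(tot))
    if (is.finite(loglik) && abs(ll - loglik) < 1e-6) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    mu <- colSums(resp * values) / nk
    sdv <- sqrt(colSums(resp * (outer(values, mu, "-"))^2) / nk)
    sdv <- pmax(sdv, sd_floor)
    w <- nk / n
  }
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; w <- w[ord]; resp <- resp[, ord, drop = FALSE]
  pooled <- sqrt(sum(w * sdv^2))
  structure(list(means = mu, sds = sdv, weights = w, responsibilities = resp,
                 separation = abs(diff(mu)) / pooled, converged = converged,
                 n_iter = iter, loglik = loglik),
            class = "mixture_fit")
}

#' Flag vasculature-contaminated voxels
#'
#' Two criteria, each gated on mixture bimodality (separation >= 2 pooled
#' SDs): voxels assigned by maximum responsibility to the higher-mean
#' component of the per-voxel mean-beta mixture, and voxels assigned to the
#' lower-mean component of the detrended mean-EPI mixture. A criterion whose
#' mixture does not pass the gate contributes no exclusions.
#'
#' @param table A [laminar_voxel_table()].
#' @param separation_gate Minimum mixture separation for a criterion to apply.
#' @return A list of class `vasculature_flags` with logical `mask` (TRUE =
#'   exclude), both `mixture_fit`s, and the per-criterion masks.
#' @export
flag_vasculature <- function(table, separation_gate = 2) {
  stopifnot(inherits(table, "laminar_voxel_table"))
  mean_beta <- rowMeans(table$betas)
  beta_fit <- fit_two_gaussian_mixture(mean_beta)
  epi_res <- detrend_epi(table$mean_epi, table$coords)
  epi_fit <- fit_two_gaussian_mixture(epi_res)
  n <- nrow(table$betas)
  beta_mask <- rep(FALSE, n)
  epi_mask <- rep(FALSE, n)
  if (beta_fit$separation >= separation_gate) {
    beta_mask <- max.col(beta_fit$responsibilities) == 2L  # higher-mean comp
  }
  if (epi_fit$separation >= separation_gate) {
    epi_mask <- max.col(epi_fit$responsibilities) == 1L    # lower-mean comp
  }
  structure(list(mask = beta_mask | epi_mask, beta_fit = beta_fit,
                 epi_fit = epi_fit, beta_mask = beta_mask, epi_mask = epi_mask),
            class = "vasculature_flags")
}

#' Assign each voxel to a cortical layer by dominant volume fraction
#'
#' A voxel is `excluded` when its WM or CSF fraction exceeds every cortical
#' layer fraction; otherwise it gets the argmax layer among deep, middle and
#' superficial, with ties broken by the fixed priority deep > middle >
#' superficial (and cortex preferred over WM/CSF on exact ties).
#'
#' @param layer_fractions Voxel x 5 matrix (`wm`, `csf`, `deep`, `middle`,
#'   `superficial`), rows summing to 1.
#' @return Character vector in `{deep, middle, superficial, excluded}`.
#' @export
assign_layer <- function(layer_fractions) {
  layer_fractions <- as.matrix(layer_fractions)
  if (is.null(colnames(layer_fractions))) colnames(layer_fractions) <- LAYER_COLS
  if (any(layer_fractions < 0)) stop("layer fractions must be non-negative")
  cort <- layer_fractions[, CORTICAL_LAYERS, drop = FALSE]
  best_cort <- max.col(cort, ties.method = "first")  # priority deep > middle > sup
  cort_max <- cort[cbind(seq_len(nrow(cort)), best_cort)]
  non_cort_max <- pmax(layer_fractions[, "wm"], layer_fractions[, "csf"])
  ifelse(non_cort_max > cort_max, "excluded", CORTICAL_LAYERS[best_cort])
}

#' Rank voxels by two-sample t-value on training blocks
#'
#' Pooled-variance two-sample t between the two classes, computed on the
#' training samples only; voxels are ranked by absolute t. If fewer than `k`
#' voxels are available, all are returned (ranked).
#'
#' @param train_betas Voxel x sample matrix of training responses.
#' @param labels Per-sample class labels (2 classes).
#' @param k Number of voxels to select.
#' @return Integer indices of the selected voxels, strongest first.
#' @export
select_voxels_by_t <- function(train_betas, labels, k) {
  if (k < 1) stop("`k` must be at least 1")
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("training blocks must contain exactly 2 classes")
  a <- train_betas[, labels == cls[1], drop = FALSE]
  b <- train_betas[, labels == cls[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2); v2 <- rowSums((b - m2)^2)
  sp <- sqrt((v1 + v2) / (n1 + n2 - 2)) * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / sp
  t[sp == 0 & m1 == m2] <- 0
  t[sp == 0 & m1 != m2] <- Inf
  ord <- order(abs(t), decreasing = TRUE)
  ord[seq_len(min(k, length(ord)))]
}

#' Leave-one-run-out decoding of a laminar voxel table
#'
#' Per fold, one run is held out; same-condition blocks within each training
#' run are averaged to one sample per condition per run. The vasculature mask
#' (computed once per table from condition-agnostic statistics) and the
#' optional layer restriction are applied, the top-`k` voxels by training
#' |t| are selected, columns are mean-centered with training means, and a
#' linear SVM (C = 1) classifies the held-out run's per-condition averages.
#' When `target = "category"` both orientations contribute samples, and vice
#' versa. With `layer = NULL`, the whole-ROI accuracy and the three per-layer
#' accuracies are all computed.
#'
#' @param table A [laminar_voxel_table()].
#' @param target `"category"` or `"orientation"`.
#' @param task `"peripheral"` or `"foveal"`.
#' @param layer Optional layer restriction (`"deep"`, `"middle"`,
#'   `"superficial"`); `NULL` decodes the whole ROI.
#' @param layers With `layer = NULL`, also compute the three per-layer
#'   accuracies (`per_layer`).
#' @param k Voxels to select; defaults to 500 for the whole ROI and 300
#'   within a layer.
#' @param cost SVM regularization constant.
#' @param vasc Optional precomputed [flag_vasculature()] result.
#' @return An object of class `decoding_result` with `accuracy`, `per_layer`,
#'   `n_folds`, `chance`, `n_voxels_used`, `target`, `task`.
#' @export
decode_leave_one_run_out <- function(table, target = c("category", "orientation"),
                                     task = c("peripheral", "foveal"),
                                     layer = NULL, k = NULL, cost = 1,
                                     vasc = NULL, layers = FALSE) {
  stopifnot(inherits(table, "laminar_voxel_table"))
  target <- match.arg(target)
  task <- match.arg(task)
  if (is.null(vasc)) vasc <- flag_vasculature(table)
  per_layer <- NULL
  layer_labels <- assign_layer(table$layer_fractions)
  if (is.null(layer)) {
    res <- decode_one_restriction(table, target, task, NULL, k %||% 500L,
                                  cost, vasc$mask, layer_labels)
    if (isTRUE(layers)) {
      per_layer <- vapply(CORTICAL_LAYERS, function(l) {
        decode_one_restriction(table, target, task, l, 300L, cost,
                               vasc$mask, layer_labels)$accuracy
      }, numeric(1))
    }
  } else {
    layer <- match.arg(layer, CORTICAL_LAYERS)
    res <- decode_one_restriction(table, target, task, layer, k %||% 300L,
                                  cost, vasc$mask, layer_labels)
  }
  structure(list(accuracy = res$accuracy, per_layer = per_layer,
                 n_folds = res$n_folds, chance = 0.5,
                 n_voxels_used = res$n_voxels_used, target = target,
                 task = task, layer = layer), class = "decoding_result")
}

decode_one_restriction <- function(table, target, task, layer, k, cost,
                                   excl_mask, layer_labels) {
  bi <- table$block_info
  sel_blocks <- which(bi$task == task)
  bi <- bi[sel_blocks, , drop = FALSE]
  keep_vox <- which(!excl_mask &
                      (if (is.null(layer)) TRUE else layer_labels == layer))
  if (length(keep_vox) < 2) {
    stop(sprintf("fewer than 2 voxels available after exclusion%s",
                 if (is.null(layer)) "" else sprintf(" in layer %s", layer)))
  }
  betas <- table$betas[keep_vox, sel_blocks, drop = FALSE]
  runs <- sort(unique(bi$run))
  cond <- interaction(bi$category, bi$orientation, drop = TRUE)
  labels <- as.character(bi[[target]])
  lv <- sort(unique(labels))
  # Average same-condition blocks within each run -> one sample per
  # (run, condition).
  cell <- interaction(bi$run, cond, drop = TRUE)
  cell_levels <- levels(cell)
  M <- vapply(cell_levels, function(cl) {
    idx <- which(cell == cl)
    rowMeans(betas[, idx, drop = FALSE])
  }, numeric(nrow(betas)))
  cell_run <- bi$run[match(cell_levels, as.character(cell))]
  cell_lab <- labels[match(cell_levels, as.character(cell))]
  n_correct <- 0L
  n_total <- 0L
  n_used <- integer(0)
  for (r in runs) {
    tr <- which(cell_run != r)
    te <- which(cell_run == r)
    tr_lab <- cell_lab[tr]
    missing <- setdiff(lv, unique(tr_lab))
    if (length(missing)) {
      stop(sprintf("training fold for run %s is missing class %s", r,
                   missing[1]))
    }
    vox <- select_voxels_by_t(M[, tr, drop = FALSE], tr_lab, k)
    Xtr <- t(M[vox, tr, drop = FALSE])
    Xte <- t(M[vox, te, drop = FALSE])
    mu <- colMeans(Xtr)
    Xtr <- sweep(Xtr, 2, mu)
    Xte <- sweep(Xte, 2, mu)
    fit <- fit_linear_svm(Xtr, factor(tr_lab, levels = lv), cost = cost)
    pred <- svm_predict(fit, Xte, lv)
    n_correct <- n_correct + sum(pred == cell_lab[te], na.rm = TRUE)
    n_total <- n_total + length(te)
    n_used <- c(n_used, length(vox))
  }
  list(accuracy = n_correct / n_total, n_folds = length(runs),
       n_voxels_used = mean(n_used))
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s/%s: accuracy %.3f (chance %.2f, %d folds)\n",
              x$task, x$target, x$accuracy, x$chance, x$n_folds))
  if (!is.null(x$per_layer)) {
    cat("  layers:", paste(sprintf("%s %.3f", names(x$per_layer), x$per_layer),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
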