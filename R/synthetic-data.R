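# Synthetic laminar fMRI tables and MEG-like epoch sets with planted ground
# truth. The generators define the study conditions every downstream stage is
# validated against: layer-specific information profiles, vein-contaminated
# voxel subpopulations, location-specific feedforward patterns, a delayed
# location-invariant feedback pattern whose trial gain is a lagged copy of the
# occipitotemporal gain series, and reaction times that depend on feedback
# strength.

CORTICAL_LAYERS <- c("deep", "middle", "superficial")
LAYER_COLS <- c("wm", "csf", CORTICAL_LAYERS)
FEATURES <- c("category", "orientation")
CATEGORY_LEVELS <- c("cubie", "smoothie")
ORIENTATION_LEVELS <- c("vertical", "horizontal")
LOCATION_SETS <- c("A", "B")

#' Default layer-wise information profile for the fMRI generator
#'
#' Encodes the qualitative laminar map the generator plants: in foveal V1,
#' category information in deep and superficial layers (feedback) and
#' orientation in the deep layer only; in peripheral V1, orientation in middle
#' and superficial layers (feedforward) and no category information; in LOC and
#' pIPS, category information in middle and superficial layers.
#'
#' @param amplitude Pattern amplitude in response units for every non-zero
#'   entry. The default of 3 is three times the default beta noise SD.
#' @return A data frame with columns `roi`, `layer`, `feature`, `amplitude`.
#' @export
default_info_profile <- function(amplitude = 3) {
  stopifnot(is.finite(amplitude), amplitude >= 0)
  entries <- rbind(
    data.frame(roi = "foveal_v1", layer = c("deep", "superficial"), feature = "category"),
    data.frame(roi = "foveal_v1", layer = "deep", feature = "orientation"),
    data.frame(roi = "peripheral_v1", layer = c("middle", "superficial"), feature = "orientation"),
    data.frame(roi = "loc", layer = c("middle", "superficial"), feature = "category"),
    data.frame(roi = "pips", layer = c("middle", "superficial"), feature = "category")
  )
  entries$amplitude <- amplitude
  entries
}

#' Configuration for the laminar fMRI generator
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_runs Task runs per subject; each run holds one block per condition
#'   per task (8 blocks per run).
#' @param rois Named integer vector of voxels per ROI.
#' @param info_profile Data frame (`roi`, `layer`, `feature`, `amplitude`)
#'   giving the pattern amplitude carried by each cortical layer, in response
#'   units; see [default_info_profile()].
#' @param vein_fraction Proportion of voxels per ROI drawn from the
#'   vein-contaminated subpopulation; must be below 0.5.
#' @param vein_beta_shift Additive shift of vein-voxel betas (response units).
#' @param vein_epi_shift Additive shift of vein-voxel mean EPI intensity
#'   (intensity units; negative, veins are dark in T2*-weighted EPI).
#' @param epi_trend_slope Linear spatial trend of mean EPI per coordinate unit.
#' @param noise_sd Beta noise SD in response units.
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#' @return An object of class `fmri_sim_config`.
#' @export
fmri_sim_config <- function(n_subjects = 18,
                            n_runs = 12,
                            rois = c(foveal_v1 = 600, peripheral_v1 = 600,
                                     loc = 600, pips = 600),
                            info_profile = default_info_profile(),
                            vein_fraction = 0.1,
                            vein_beta_shift = 1,
                            vein_epi_shift = -150,
                            epi_trend_slope = 5,
                            noise_sd = 1,
                            seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("`seed` must be a single integer")
  }
  stopifnot(n_subjects >= 1, n_runs >= 1, all(rois >= 1))
  if (is.null(names(rois)) || any(!nzchar(names(rois)))) stop("`rois` must be named")
  if (vein_fraction < 0 || vein_fraction >= 0.5) {
    stop("`vein_fraction` must lie in [0, 0.5)")
  }
  stopifnot(is.data.frame(info_profile),
            all(c("roi", "layer", "feature", "amplitude") %in% names(info_profile)),
            all(is.finite(info_profile$amplitude)), all(info_profile$amplitude >= 0),
            all(info_profile$layer %in% CORTICAL_LAYERS),
            all(info_profile$feature %in% FEATURES))
  structure(list(
    n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
    rois = rois, info_profile = info_profile,
    vein_fraction = vein_fraction, vein_beta_shift = vein_beta_shift,
    vein_epi_shift = vein_epi_shift, epi_trend_slope = epi_trend_slope,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "fmri_sim_config")
}

#' Default feedforward onsets for the MEG generator
#'
#' Early visual cortex leads, followed by the dorsal (posterior parietal) and
#' ventral (occipitotemporal) regions; seconds after stimulus onset.
#'
#' @return Data frame with columns `region`, `feature`, `onset`.
#' @export
default_ff_onsets <- function() {
  data.frame(
    region = rep(c("evc", "otc", "ppc"), each = 2),
    feature = rep(FEATURES, 3),
    onset = c(0.06, 0.06, 0.13, 0.14, 0.11, 0.14)
  )
}

#' Default pathway amplitudes for the MEG generator
#'
#' Feedforward patterns in all three regions; the feedback pathway carries a
#' location-invariant pattern into early visual cortex only.
#'
#' @return Data frame with columns `region`, `feature`, `pathway`, `amplitude`.
#' @export
default_meg_amplitudes <- function() {
  amp <- expand.grid(region = c("evc", "otc", "ppc"), feature = FEATURES,
                     pathway = c("feedforward", "feedback"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  amp$amplitude <- ifelse(amp$pathway == "feedforward",
                          ifelse(amp$region == "evc", 1.5, 1.2),
                          ifelse(amp$region == "evc", 1.5, 0))
  amp
}

#' Configuration for the MEG-like epoch generator
#'
#' @param sfreq Sampling frequency in Hz.
#' @param epoch_window Epoch limits `(t_min, t_max)` in seconds relative to
#'   stimulus onset; must contain `[-0.2, 0]` for the pre-stimulus Granger
#'   baseline.
#' @param n_trials_per_condition Trials for every condition at each location
#'   set (condition = category x orientation).
#' @param regions Named integer vector of sources per region; names are used
#'   in the feature-to-region map of the generated epochs.
#' @param ff_onsets Data frame (`region`, `feature`, `onset` seconds) of
#'   feedforward envelope onsets; see [default_ff_onsets()].
#' @param fb_onset Named numeric: feedback envelope onset (seconds) per
#'   feature.
#' @param fb_lag Lag (seconds) between the occipitotemporal per-trial gain
#'   series and the early-visual feedback gain; must be a multiple of
#'   `1/sfreq` and lie within `[1, 5]` samples so that the default
#'   autoregressive model order can resolve it.
#' @param amplitudes Data frame (`region`, `feature`, `pathway`, `amplitude`);
#'   see [default_meg_amplitudes()].
#' @param gain_sd SD of the log per-trial gain fluctuation (unitless).
#' @param gain_smooth_s Gaussian SD (seconds) used to smooth the gain series
#'   in time. The default of 0 keeps the gains white in time, so the planted
#'   coupling is strictly causal at the stated lag: with autocorrelated gains
#'   the noisy occipitotemporal series predicts the early-visual series in
#'   *both* time directions (a measurement-noise replica effect), which
#'   contaminates direction-specificity controls.
#' @param rt_intercept,rt_slope,rt_noise_sd Reaction-time model: `rt =
#'   rt_intercept - rt_slope * feedback_strength + noise`, floored at 0.2 s.
#' @param noise_sd Sensor/source noise SD in signal units.
#' @param seed Integer RNG seed.
#' @return An object of class `meg_sim_config`.
#' @export
meg_sim_config <- function(sfreq = 100,
                           epoch_window = c(-0.3, 0.8),
                           n_trials_per_condition = 104,
                           regions = c(evc = 60, otc = 60, ppc = 60),
                           ff_onsets = default_ff_onsets(),
                           fb_onset = c(category = 0.22, orientation = 0.25),
                           fb_lag = 0.03,
                           amplitudes = default_meg_amplitudes(),
                           gain_sd = 0.7,
                           gain_smooth_s = 0,
                           rt_intercept = 0.9,
                           rt_slope = 0.3,
                           rt_noise_sd = 0.1,
                           noise_sd = 1,
                           seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("`seed` must be a single integer")
  }
  stopifnot(sfreq > 0, n_trials_per_condition >= 1, all(regions >= 6))
  if (is.null(names(regions))) stop("`regions` must be named")
  if (!(epoch_window[1] <= -0.2 && epoch_window[2] >= 0)) {
    stop("`epoch_window` must contain [-0.2, 0] for the pre-stimulus baseline")
  }
  lag_samples <- fb_lag * sfreq
  if (abs(lag_samples - round(lag_samples)) > 1e-9) {
    stop("`fb_lag` must be a multiple of 1/sfreq")
  }
  if (round(lag_samples) < 1 || round(lag_samples) > 5) {
    stop("`fb_lag` must lie within [1/sfreq, 5/sfreq]")
  }
  stopifnot(all(FEATURES %in% names(fb_onset)))
  evc_ff <- ff_onsets$onset[ff_onsets$region == names(regions)[1]]
  if (length(evc_ff) && any(fb_onset <= max(evc_ff))) {
    stop("`fb_onset` must exceed every feedforward onset in early visual cortex")
  }
  structure(list(
    sfreq = sfreq, epoch_window = epoch_window,
    n_trials_per_condition = as.integer(n_trials_per_condition),
    regions = regions, ff_onsets = ff_onsets, fb_onset = fb_onset,
    fb_lag = fb_lag, amplitudes = amplitudes, gain_sd = gain_sd,
    gain_smooth_s = gain_smooth_s, rt_intercept = rt_intercept,
    rt_slope = rt_slope, rt_noise_sd = rt_noise_sd, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "meg_sim_config")
}

#' Default generator configuration matching the study design
#'
#' Structural constants follow the experimental design: 12 task runs with one
#' block per condition per task in the fMRI arm; 100 Hz sampling and 104
#' trials per condition at each location set in the MEG arm; four fMRI ROIs
#' (foveal V1, peripheral V1, LOC, pIPS) and three MEG regions (early visual,
#' occipitotemporal, posterior parietal cortex).
#'
#' @param kind `"fmri"` or `"meg"`.
#' @return An [fmri_sim_config()] or [meg_sim_config()].
#' @export
default_paper_config <- function(kind) {
  switch(match.arg(kind, c("fmri", "meg")),
         fmri = fmri_sim_config(),
         meg = meg_sim_config())
}

# Dirichlet layer fractions concentrated on one randomly chosen layer per
# voxel: dominant alpha 8, others 0.5 (dominant fraction 0.8 in expectation).
random_layer_fractions <- function(n_voxels) {
  dominant <- sample.int(5L, n_voxels, replace = TRUE)
  alpha <- matrix(0.5, n_voxels, 5)
  alpha[cbind(seq_len(n_voxels), dominant)] <- 8
  g <- matrix(stats::rgamma(n_voxels * 5, shape = alpha), n_voxels, 5)
  frac <- g / rowSums(g)
  colnames(frac) <- LAYER_COLS
  frac
}

# Block design: one block per condition per task per run.
make_block_info <- function(n_runs) {
  bi <- expand.grid(orientation = ORIENTATION_LEVELS, category = CATEGORY_LEVELS,
                    task = c("peripheral", "foveal"), run = seq_len(n_runs),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bi[, c("run", "task", "category", "orientation")]
}

#' Generate laminar fMRI voxel tables with planted ground truth
#'
#' Per subject and ROI, one beta sample per (run, task, condition) block.
#' Condition effects are added along a fixed unit pattern vector, weighted per
#' voxel by its volume fraction of the layers carrying that feature in the
#' information profile. Vein voxels get a positive beta shift, doubled beta
#' noise SD, and a negative mean-EPI shift; mean EPI carries a linear spatial
#' trend plus noise.
#'
#' @param config An [fmri_sim_config()].
#' @return A list with `subjects` (per subject, a named list of
#'   `laminar_voxel_table` objects, one per ROI) and `ground_truth` holding
#'   vein masks, pattern vectors, and the information profile.
#' @export
generate_laminar_fmri <- function(config) {
  stopifnot(inherits(config, "fmri_sim_config"))
  set.seed(config$seed)
  block_info <- make_block_info(config$n_runs)
  n_blocks <- nrow(block_info)
  sign_of <- list(
    category = ifelse(block_info$category == CATEGORY_LEVELS[1], 1, -1),
    orientation = ifelse(block_info$orientation == ORIENTATION_LEVELS[1], 1, -1)
  )
  subjects <- vector("list", config$n_subjects)
  gt_masks <- vector("list", config$n_subjects)
  gt_patterns <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    tables <- list()
    masks <- list()
    pats <- list()
    for (roi in names(config$rois)) {
      nv <- config$rois[[roi]]
      frac <- random_layer_fractions(nv)
      coords <- matrix(stats::runif(nv * 3, -10, 10), nv, 3,
                       dimnames = list(NULL, c("x", "y", "z")))
      n_vein <- round(nv * config$vein_fraction)
      vein <- rep(FALSE, nv)
      if (n_vein > 0) vein[sample.int(nv, n_vein)] <- TRUE
      sd_vec <- ifelse(vein, 2 * config$noise_sd, config$noise_sd)
      betas <- matrix(stats::rnorm(nv * n_blocks, sd = rep(sd_vec, n_blocks)),
                      nv, n_blocks)
      betas[vein, ] <- betas[vein, , drop = FALSE] + config$vein_beta_shift
      roi_pat <- list()
      for (feat in FEATURES) {
        prof <- config$info_profile[config$info_profile$roi == roi &
                                      config$info_profile$feature == feat, ]
        p <- stats::rnorm(nv)
        p <- p / sqrt(sum(p^2))
        roi_pat[[feat]] <- p
        if (nrow(prof)) {
          w <- rowSums(frac[, prof$layer, drop = FALSE] *
                         rep(prof$amplitude, each = nv))
          betas <- betas + (w * p) %o% sign_of[[feat]]
        }
      }
      mean_epi <- 1000 + config$epi_trend_slope * rowSums(coords) +
        stats::rnorm(nv, sd = 20)
      mean_epi[vein] <- mean_epi[vein] + config$vein_epi_shift
      tables[[roi]] <- laminar_voxel_table(betas, block_info, frac, mean_epi,
                                           coords, roi)
      masks[[roi]] <- vein
      pats[[roi]] <- roi_pat
    }
    subjects[[s]] <- tables
    gt_masks[[s]] <- masks
    gt_patterns[[s]] <- pats
  }
  list(subjects = subjects,
       ground_truth = list(vein_mask = gt_masks, patterns = gt_patterns,
                           info_profile = config$info_profile))
}

# Raised-cosine envelope: 50 ms rise, 300 ms sustain, 100 ms fall.
response_envelope <- function(times, onset,
                              rise = 0.05, sustain = 0.3, fall = 0.1) {
  env <- numeric(length(times))
  u <- times - onset
  in_rise <- u >= 0 & u < rise
  env[in_rise] <- 0.5 * (1 - cos(pi * u[in_rise] / rise))
  env[u >= rise & u <= rise + sustain] <- 1
  in_fall <- u > rise + sustain & u < rise + sustain + fall
  env[in_fall] <- 0.5 * (1 + cos(pi * (u[in_fall] - rise - sustain) / fall))
  env
}

# Smoothed, exponentiated positive gain series (trial x time). The smoothed
# Gaussian noise is rescaled so the log-gain SD equals gain_sd.
random_gain_series <- function(n_trials, times, sfreq, gain_sd, smooth_s) {
  z <- matrix(stats::rnorm(n_trials * length(times)), n_trials)
  if (smooth_s > 0 && gain_sd > 0) {
    sigma <- smooth_s * sfreq
    half <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    zs <- t(apply(z, 1, function(r) reflect_convolve(r, k)))
    zs <- zs / sqrt(sum(k^2))  # restore unit marginal SD
    z <- zs
  }
  exp(gain_sd * z)
}

# Convolution with reflected-boundary padding (shared with gaussian_smooth).
reflect_convolve <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[pmin(pmax(half:1, 1L), n)], x, x[pmin(pmax(n - (1:half) + 0, 1L), n)])
  out <- stats::filter(pad, kernel, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Generate MEG-like epoch sets with planted ground truth
#'
#' Each trial's data are noise plus, per region and feature, a class-signed
#' spatial pattern times a raised-cosine temporal envelope times a positive
#' per-trial gain. Feedforward patterns in early visual and posterior parietal
#' cortex differ across (are orthogonal between) the two location sets;
#' occipitotemporal patterns are location-invariant. The early-visual feedback
#' component uses a location-invariant pattern, orthogonal to the same-region
#' feedforward patterns, whose per-trial gain is the occipitotemporal gain
#' series delayed by `fb_lag` -- the coupling that conditional Granger
#' causality must recover. Reaction times decrease with the planted feedback
#' strength of the category feature; correctness probability increases with it.
#'
#' @param config A [meg_sim_config()].
#' @return A list with `subjects` (list of `epoch_set`) and `ground_truth`
#'   (onsets, lag, patterns, per-trial gain series, planted feedback strength).
#' @export
generate_meg_epochs <- function(config) {
  stopifnot(inherits(config, "meg_sim_config"))
  set.seed(config$seed)
  sfreq <- config$sfreq
  times <- seq.int(round(config$epoch_window[1] * sfreq),
                   round(config$epoch_window[2] * sfreq)) / sfreq
  n_time <- length(times)
  region_names <- names(config$regions)
  evc <- region_names[1]; otc <- region_names[2]
  feature_region <- rep(region_names, config$regions)
  n_feat_total <- length(feature_region)
  trial_table0 <- expand.grid(
    rep_i = seq_len(config$n_trials_per_condition),
    orientation = ORIENTATION_LEVELS, category = CATEGORY_LEVELS,
    location_set = LOCATION_SETS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trial_table0$rep_i <- NULL
  n_trials <- nrow(trial_table0)
  lag_samp <- as.integer(round(config$fb_lag * sfreq))
  amp_of <- function(region, feat, pathway) {
    a <- config$amplitudes
    v <- a$amplitude[a$region == region & a$feature == feat & a$pathway == pathway]
    if (length(v)) v[1] else 0
  }
  onset_of <- function(region, feat) {
    o <- config$ff_onsets
    o$onset[o$region == region & o$feature == feat][1]
  }
  gt <- list(ff_onsets = config$ff_onsets, fb_onset = config$fb_onset,
             fb_lag = config$fb_lag, patterns = list(), gains = list(),
             fb_strength = list(), trial_order = list())
  n_subj <- 1L
  out_subjects <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    ord <- sample.int(n_trials)  # randomize trial order
    trial_table <- trial_table0[ord, , drop = FALSE]
    rownames(trial_table) <- NULL
    sign_feat <- list(
      category = ifelse(trial_table$category == CATEGORY_LEVELS[1], 1, -1),
      orientation = ifelse(trial_table$orientation == ORIENTATION_LEVELS[1], 1, -1))
    is_loc <- lapply(stats::setNames(LOCATION_SETS, LOCATION_SETS),
                     function(l) trial_table$location_set == l)
    # Orthonormal patterns per region: per feature, ff(A), ff(B), fb.
    patterns <- list()
    for (r in region_names) {
      nf <- config$regions[[r]]
      q <- qr.Q(qr(matrix(stats::rnorm(nf * 6), nf, 6)))
      pr <- list()
      for (fi in seq_along(FEATURES)) {
        feat <- FEATURES[fi]
        cols <- (fi - 1L) * 3L
        if (r == otc) {
          ffA <- q[, cols + 1]; ffB <- ffA  # location-invariant feedforward
        } else {
          ffA <- q[, cols + 1]; ffB <- q[, cols + 2]
        }
        pr[[feat]] <- list(feedforward = list(A = ffA, B = ffB),
                           feedback = q[, cols + 3])
      }
      patterns[[r]] <- pr
    }
    data <- array(stats::rnorm(n_trials * n_feat_total * n_time,
                               sd = config$noise_sd),
                  dim = c(n_trials, n_feat_total, n_time))
    gains <- list()
    for (r in region_names) {
      for (feat in FEATURES) {
        gains[[paste(r, feat, sep = ".")]] <-
          random_gain_series(n_trials, times, sfreq, config$gain_sd,
                             config$gain_smooth_s)
      }
    }
    add_component <- function(data, region, pattern, contrib) {
      idx <- which(feature_region == region)
      for (v in seq_along(idx)) {
        data[, idx[v], ] <- data[, idx[v], ] + pattern[v] * contrib
      }
      data
    }
    for (r in region_names) {
      for (feat in FEATURES) {
        a_ff <- amp_of(r, feat, "feedforward")
        if (a_ff > 0) {
          env <- response_envelope(times, onset_of(r, feat))
          g <- gains[[paste(r, feat, sep = ".")]]
          base <- a_ff * sign_feat[[feat]] * g *
            rep(env, each = n_trials)
          for (l in LOCATION_SETS) {
            contrib <- base
            contrib[!is_loc[[l]], ] <- 0
            data <- add_component(data, r, patterns[[r]][[feat]]$feedforward[[l]],
                                  contrib)
          }
        }
        a_fb <- amp_of(r, feat, "feedback")
        if (a_fb > 0) {
          env_fb <- response_envelope(times, config$fb_onset[[feat]])
          g_src <- gains[[paste(otc, feat, sep = ".")]]
          g_fb <- cbind(g_src[, rep(1L, lag_samp), drop = FALSE],
                        g_src[, seq_len(n_time - lag_samp), drop = FALSE])
          contrib <- a_fb * sign_feat[[feat]] * g_fb * rep(env_fb, each = n_trials)
          data <- add_component(data, r, patterns[[r]][[feat]]$feedback, contrib)
        }
      }
    }
    # Behavior: RT decreases with planted category feedback strength.
    env_fb <- response_envelope(times, config$fb_onset[["category"]])
    win <- times >= config$fb_onset[["category"]] &
      times <= config$fb_onset[["category"]] + 0.2
    g_src <- gains[[paste(otc, "category", sep = ".")]]
    g_fb <- cbind(g_src[, rep(1L, lag_samp), drop = FALSE],
                  g_src[, seq_len(n_time - lag_samp), drop = FALSE])
    a_fb_cat <- amp_of(evc, "category", "feedback")
    fb_strength <- a_fb_cat *
      rowMeans(g_fb[, win, drop = FALSE] * rep(env_fb[win], each = n_trials))
    rt <- config$rt_intercept - config$rt_slope * fb_strength +
      stats::rnorm(n_trials, sd = config$rt_noise_sd)
    rt <- pmax(rt, 0.2)
    p_correct <- stats::plogis(0.73 + 1.5 * (fb_strength - mean(fb_strength)))
    if (a_fb_cat == 0) p_correct <- rep(stats::plogis(0.73), n_trials)
    correct <- stats::rbinom(n_trials, 1, p_correct) == 1
    trial_table$rt <- rt
    trial_table$correct <- correct
    out_subjects[[s]] <- epoch_set(data, times, sfreq, trial_table, feature_region)
    gt$patterns[[s]] <- patterns
    gt$gains[[s]] <- gains
    gt$fb_strength[[s]] <- fb_strength
    gt$trial_order[[s]] <- ord
  }
  list(subjects = out_subjects, ground_truth = gt)
}

#' Generate several MEG subjects from one configuration
#'
#' Convenience wrapper: subject `s` uses `config$seed + s - 1` so replicate
#' experiments across seeds stay disjoint.
#'
#' @param config A [meg_sim_config()].
#' @param n_subjects Number of subjects.
#' @return As [generate_meg_epochs()], with one entry per subject.
#' @export
generate_meg_subjects <- function(config, n_subjects) {
  subjects <- vector("list", n_subjects)
  gt <- NULL
  for (s in seq_len(n_subjects)) {
    cfg_s <- config
    cfg_s$seed <- config$seed + s - 1L
    res <- generate_meg_epochs(cfg_s)
    subjects[[s]] <- res$subjects[[1]]
    if (is.null(gt)) {
      gt <- res$ground_truth
    } else {
      gt$patterns[[s]] <- res$ground_truth$patterns[[1]]
      gt$gains[[s]] <- res$ground_truth$gains[[1]]
      gt$fb_strength[[s]] <- res$ground_truth$fb_strength[[1]]
      gt$trial_order[[s]] <- res$ground_truth$trial_order[[1]]
    }
  }
  list(subjects = subjects, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
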