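# S3 containers for the two input kinds and printers. Validation happens at
# construction so analysis code can rely on the invariants.

#' Construct a laminar voxel table
#'
#' Block-wise voxel responses for one ROI of one subject, with per-voxel layer
#' volume fractions, mean EPI intensity, and coordinates.
#'
#' @param betas Numeric matrix, voxel x block, in response units.
#' @param block_info Data frame with one row per block and columns `run`,
#'   `task` (`"peripheral"`/`"foveal"`), `category`, `orientation`; every
#'   (run, task, category, orientation) cell must hold exactly one block.
#' @param layer_fractions Voxel x 5 matrix with columns `wm`, `csf`, `deep`,
#'   `middle`, `superficial`; rows must sum to 1.
#' @param mean_epi Per-voxel mean EPI intensity.
#' @param coords Voxel x 3 coordinate matrix (mm).
#' @param roi ROI name.
#' @return An object of class `laminar_voxel_table`.
#' @export
laminar_voxel_table <- function(betas, block_info, layer_fractions, mean_epi,
                                coords, roi) {
  betas <- as.matrix(betas)
  layer_fractions <- as.matrix(layer_fractions)
  coords <- as.matrix(coords)
  if (anyNA(betas)) stop("`betas` must not contain NA")
  if (nrow(block_info) != ncol(betas)) {
    stop("`block_info` must have one row per beta column")
  }
  stopifnot(nrow(layer_fractions) == nrow(betas),
            ncol(layer_fractions) == 5,
            length(mean_epi) == nrow(betas),
            nrow(coords) == nrow(betas), ncol(coords) == 3)
  if (is.null(colnames(layer_fractions))) colnames(layer_fractions) <- LAYER_COLS
  if (any(abs(rowSums(layer_fractions) - 1) > 1e-6)) {
    stop("`layer_fractions` rows must sum to 1")
  }
  cells <- table(interaction(block_info$run, block_info$task,
                             block_info$category, block_info$orientation,
                             drop = TRUE))
  if (any(cells != 1)) {
    stop("every (run, task, category, orientation) cell must have exactly one block")
  }
  structure(list(betas = betas, block_info = block_info,
                 layer_fractions = layer_fractions,
                 mean_epi = as.numeric(mean_epi), coords = coords, roi = roi),
            class = "laminar_voxel_table")
}

#' @export
print.laminar_voxel_table <- function(x, ...) {
  cat(sprintf("<laminar_voxel_table> roi=%s: %d voxels x %d blocks (%d runs)\n",
              x$roi, nrow(x$betas), ncol(x$betas),
              length(unique(x$block_info$run))))
  invisible(x)
}

#' Construct an epoch set
#'
#' Trial x feature x time array of source-space responses with condition and
#' behavior labels and a feature-to-region map.
#'
#' @param data 3-D numeric array, trial x feature x time.
#' @param times Sample times in seconds, stimulus onset at 0; must be
#'   strictly increasing and uniform at `1/sfreq`.
#' @param sfreq Sampling frequency (Hz).
#' @param trial_table Data frame with one row per trial and columns
#'   `category`, `orientation`, `location_set` (`"A"`/`"B"`), `rt` (seconds,
#'   `NA` allowed), `correct` (logical).
#' @param feature_region Character vector mapping each feature (source) to a
#'   region name.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, trial_table, feature_region) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == nrow(trial_table),
            dim(data)[2] == length(feature_region),
            dim(data)[3] == length(times))
  dt <- diff(times)
  if (any(dt <= 0) || any(abs(dt - 1 / sfreq) > 1e-9)) {
    stop("`times` must be strictly increasing and uniform at 1/sfreq")
  }
  needed <- c("category", "orientation", "location_set")
  stopifnot(all(needed %in% names(trial_table)))
  cells <- table(interaction(trial_table$category, trial_table$orientation,
                             trial_table$location_set, drop = FALSE))
  if (any(cells == 0)) stop("every (condition, location_set) cell must be nonempty")
  structure(list(data = data, times = times, sfreq = sfreq,
                 trial_table = trial_table,
                 feature_region = as.character(feature_region)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d features x %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq,
    min(x$times), max(x$times)))
  cat("  regions:", paste(sprintf("%s(%d)", names(table(x$feature_region)),
                                  table(x$feature_region)), collapse = ", "), "\n")
  invisible(x)
}
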