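# Containers, configuration, result writers and the pipeline runner tying
# the stages together: simulate -> fmri-decode -> meg-decode -> infoflow ->
# behavior -> stats.

CONTAINER_SCHEMA_VERSION <- 1L

#' Save generated data to a container file
#'
#' Single-file container (RDS serialization) with the logical layout
#' `/fmri/<subject>/...`, `/meg/<subject>/...` and `/ground_truth`; loading
#' reproduces all arrays bit-exactly.
#'
#' @param path Destination file path.
#' @param fmri Optional list of per-subject ROI-table lists from
#'   [generate_laminar_fmri()].
#' @param meg Optional list of per-subject [epoch_set()] objects.
#' @param ground_truth Optional ground-truth list; stored alongside the data.
#' @return `path`, invisibly.
#' @export
save_container <- function(path, fmri = NULL, meg = NULL, ground_truth = NULL) {
  obj <- list(schema_version = CONTAINER_SCHEMA_VERSION, fmri = fmri,
              meg = meg, ground_truth = ground_truth)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Load a container file
#'
#' @param path Container path written by [save_container()].
#' @param require Character vector of groups that must be present
#'   (subset of `"fmri"`, `"meg"`, `"ground_truth"`); a missing group raises
#'   an error naming it.
#' @return The container list.
#' @export
load_container <- function(path, require = character(0)) {
  if (!file.exists(path)) stop(sprintf("container %s does not exist", path))
  obj <- readRDS(path)
  if (!identical(obj$schema_version, CONTAINER_SCHEMA_VERSION)) {
    stop(sprintf("container schema version mismatch: file has %s, expected %d",
                 format(obj$schema_version), CONTAINER_SCHEMA_VERSION))
  }
  for (grp in require) {
    if (is.null(obj[[grp]])) stop(sprintf("container is missing /%s", grp))
  }
  obj
}

#' Default analysis configuration
#'
#' Reduced problem sizes suitable for an end-to-end smoke run; every stage
#' parameter of the analysis chain can be overridden, and stages can be
#' toggled.
#'
#' @param seed Master seed recorded in every output.
#' @return Nested list of class `analysis_config`.
#' @export
default_analysis_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = "laminarflow-results",
    stages = list(simulate = TRUE, fmri_decode = TRUE, meg_decode = TRUE,
                  infoflow = TRUE, behavior = TRUE, stats = TRUE),
    fmri = list(n_subjects = 5, rois = c(foveal_v1 = 200, peripheral_v1 = 200),
                n_runs = 12, k_roi = 500, k_layer = 300),
    meg = list(n_subjects = 5, n_trials_per_condition = 32,
               regions = c(evc = 30, otc = 30, ppc = 30),
               n_splits = 8, n_repeats = 2, k = 30, half_width = 0.1),
    gc = list(window = 0.15, order = 5),
    stats = list(n_perm = 2000, cluster_forming_p = 0.01, corrected_p = 0.01)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unspecified entries fall back to [default_analysis_config()] values.
#'
#' @param path YAML file path.
#' @return `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file %s does not exist", path))
  user <- yaml::read_yaml(path)
  cfg <- default_analysis_config(seed = user$seed %||% 1L)
  for (nm in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  for (grp in c("fmri", "meg")) {
    if (!is.null(cfg[[grp]]$rois)) cfg[[grp]]$rois <- unlist(cfg[[grp]]$rois)
    if (!is.null(cfg[[grp]]$regions)) cfg[[grp]]$regions <- unlist(cfg[[grp]]$regions)
  }
  cfg
}

#' Write a YAML analysis configuration
#'
#' @param config An `analysis_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  out <- unclass(config)
  # named vectors must become maps, not sequences, to keep their names
  for (grp in c("fmri", "meg")) {
    if (!is.null(out[[grp]]$rois)) out[[grp]]$rois <- as.list(out[[grp]]$rois)
    if (!is.null(out[[grp]]$regions)) {
      out[[grp]]$regions <- as.list(out[[grp]]$regions)
    }
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

# Stable lightweight checksum of the analysis parameters (hex string) for
# output headers; not cryptographic. The output directory is not part of the
# hash: the same analysis written elsewhere is the same analysis.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  txt <- paste(deparse(cfg, control = "all"), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 216613626
  for (b in bytes) h <- ((h * 16777619) + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# TSV with a header comment carrying seed and config hash; 6 significant
# digits for byte-stable diffs.
write_result_tsv <- function(df, path, seed, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  invisible(path)
}

log_event <- function(log, stage, message) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage,
                message = message)
  c(log, list(entry))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in order: simulate, fmri-decode (whole-ROI and
#' per-layer leave-one-run-out decoding for both targets, peripheral task),
#' meg-decode (same- and cross-location time courses per region and target),
#' infoflow (cross-location strength, conditional Granger causality in both
#' directions between occipitotemporal and early visual cortex, baseline and
#' onset), behavior (strength-RT correlation), and stats (group one-sample
#' tests with FDR and cluster permutation). Identical config and seed yield
#' identical result files.
#'
#' @param config An `analysis_config` (see [default_analysis_config()]).
#' @return Invisibly, a list with the output directory, result paths, and the
#'   run log (also written to `run_log.json`).
#' @export
run_pipeline <- function(config = default_analysis_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  log <- list()
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_result_tsv(df, p, seed, hash)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  container_path <- file.path(config$out_dir, "synthetic_data.rds")

  fmri_data <- NULL; meg_data <- NULL
  if (isTRUE(config$stages$simulate)) {
    log <- log_event(log, "simulate", "generating synthetic fMRI and MEG data")
    fmri_cfg <- fmri_sim_config(n_subjects = config$fmri$n_subjects,
                                n_runs = config$fmri$n_runs,
                                rois = config$fmri$rois, seed = seed)
    fmri_data <- generate_laminar_fmri(fmri_cfg)
    meg_cfg <- meg_sim_config(
      n_trials_per_condition = config$meg$n_trials_per_condition,
      regions = config$meg$regions, seed = seed)
    meg_data <- generate_meg_subjects(meg_cfg, config$meg$n_subjects)
    save_container(container_path, fmri = fmri_data$subjects,
                   meg = meg_data$subjects,
                   ground_truth = list(fmri = fmri_data$ground_truth,
                                       meg = meg_data$ground_truth))
  }

  fmri_rows <- NULL
  if (isTRUE(config$stages$fmri_decode)) {
    if (is.null(fmri_data)) stop("stage fmri-decode: no simulated fMRI data available")
    log <- log_event(log, "fmri-decode", "leave-one-run-out laminar decoding")
    rows <- list()
    for (s in seq_along(fmri_data$subjects)) {
      for (roi in names(fmri_data$subjects[[s]])) {
        tab <- fmri_data$subjects[[s]][[roi]]
        for (target in FEATURES) {
          res <- decode_leave_one_run_out(tab, target = target,
                                          task = "peripheral",
                                          k = config$fmri$k_roi, layers = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, roi = roi, target = target,
            layer = c("all", names(res$per_layer)),
            accuracy = c(res$accuracy, unname(res$per_layer)))
        }
      }
    }
    fmri_rows <- do.call(rbind, rows)
    emit(fmri_rows, "fmri_decoding.tsv")
  }

  meg_tcs <- NULL
  if (isTRUE(config$stages$meg_decode)) {
    if (is.null(meg_data)) stop("stage meg-decode: no simulated MEG data available")
    log <- log_event(log, "meg-decode", "time-resolved decoding")
    rows <- list()
    for (s in seq_along(meg_data$subjects)) {
      ep <- meg_data$subjects[[s]]
      for (region in names(config$meg$regions)) {
        for (scheme in c("same_location", "cross_location")) {
          tc <- decode_timecourse(ep, region, target = "category",
                                  scheme = scheme,
                                  n_splits = config$meg$n_splits,
                                  n_repeats = config$meg$n_repeats,
                                  k = config$meg$k, seed = seed + s)
          tc <- smooth_timecourse(tc, config$meg$half_width)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, region = region, target = "category",
            scheme = scheme, time = tc$times, accuracy = tc$accuracy)
        }
      }
    }
    meg_tcs <- do.call(rbind, rows)
    emit(meg_tcs, "meg_decoding.tsv")
  } else if (isTRUE(config$stages$infoflow) || isTRUE(config$stages$behavior)) {
    log <- log_event(log, "meg-decode", "stage disabled")
  }

  strengths_by_subject <- NULL
  if (isTRUE(config$stages$infoflow)) {
    if (is.null(meg_data)) {
      log <- log_event(log, "infoflow", "skipped: MEG stages disabled")
    } else {
      log <- log_event(log, "infoflow", "strength time courses and Granger causality")
      gc_rows <- list()
      gcs_fb <- list(); gcs_ff <- list()
      strengths_by_subject <- list()
      for (s in seq_along(meg_data$subjects)) {
        ep <- meg_data$subjects[[s]]
        sts <- lapply(stats::setNames(nm = names(config$meg$regions)),
                      function(r) {
          normalize_strength(strength_timecourse(
            ep, r, target = "category", scheme = "cross_location",
            n_splits = config$meg$n_splits, k = config$meg$k, seed = seed + s))
        })
        strengths_by_subject[[s]] <- sts
        rn <- names(config$meg$regions)
        gfb <- conditional_granger(sts, source = rn[2], target = rn[1],
                                   window = config$gc$window,
                                   order = config$gc$order)
        gff <- conditional_granger(sts, source = rn[1], target = rn[2],
                                   window = config$gc$window,
                                   order = config$gc$order)
        gcs_fb[[s]] <- gfb; gcs_ff[[s]] <- gff
        gc_rows[[length(gc_rows) + 1L]] <- data.frame(
          subject = s, time = gfb$times,
          gc_feedback = gfb$gc, gc_feedforward = gff$gc,
          baseline_feedback = gfb$baseline, baseline_feedforward = gff$baseline)
      }
      emit(do.call(rbind, gc_rows), "granger.tsv")
      if (length(gcs_fb) >= 5) {
        ons_fb <- gc_baseline_and_onset(gcs_fb, n_perm = config$stats$n_perm,
                                        cluster_forming_p = config$stats$cluster_forming_p,
                                        corrected_p = config$stats$corrected_p,
                                        seed = seed)
        ons_ff <- gc_baseline_and_onset(gcs_ff, n_perm = config$stats$n_perm,
                                        cluster_forming_p = config$stats$cluster_forming_p,
                                        corrected_p = config$stats$corrected_p,
                                        seed = seed)
        arrows <- list(
          feedback = list(source = names(config$meg$regions)[2],
                          target = names(config$meg$regions)[1],
                          onset_s = ons_fb$onset),
          feedforward = list(source = names(config$meg$regions)[1],
                             target = names(config$meg$regions)[2],
                             onset_s = ons_ff$onset))
        p <- file.path(config$out_dir, "granger_arrows.json")
        jsonlite::write_json(arrows, p, auto_unbox = TRUE, digits = NA,
                             na = "null")
        paths[[length(paths) + 1L]] <- p
      }
    }
  }

  if (isTRUE(config$stages$behavior)) {
    if (is.null(strengths_by_subject)) {
      log <- log_event(log, "behavior", "skipped: infoflow stage disabled")
    } else {
      log <- log_event(log, "behavior", "strength-RT correlation")
      rows <- list()
      for (s in seq_along(meg_data$subjects)) {
        ep <- meg_data$subjects[[s]]
        bc <- behavior_correlation(
          strengths_by_subject[[s]][[names(config$meg$regions)[1]]],
          ep$trial_table, half_width = config$meg$half_width)
        rows[[length(rows) + 1L]] <- data.frame(subject = s, time = bc$times,
                                                r = bc$r)
      }
      emit(do.call(rbind, rows), "behavior_correlation.tsv")
    }
  }

  if (isTRUE(config$stages$stats) && !is.null(fmri_rows)) {
    log <- log_event(log, "stats", "group tests")
    agg <- stats::aggregate(accuracy ~ roi + target + layer, fmri_rows, mean)
    tests <- lapply(seq_len(nrow(agg)), function(i) {
      vals <- fmri_rows$accuracy[fmri_rows$roi == agg$roi[i] &
                                   fmri_rows$target == agg$target[i] &
                                   fmri_rows$layer == agg$layer[i]]
      if (length(vals) >= 3 && stats::sd(vals) > 0) {
        one_sample_t(vals, mu = 0.5, tail = "one")$p
      } else NA_real_
    })
    agg$p <- unlist(tests)
    layer_rows <- agg$layer != "all"
    agg$q <- NA_real_
    if (any(layer_rows & !is.na(agg$p))) {
      idx <- which(layer_rows & !is.na(agg$p))
      agg$q[idx] <- fdr_bh(agg$p[idx], m = max(24L, length(idx)))$q
    }
    emit(agg, "group_fmri_stats.tsv")
  }

  log <- log_event(log, "done", "pipeline complete")
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(list(seed = seed, config_hash = hash,
                            parameters = unclass(config), events = log),
                       log_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(out_dir = config$out_dir, paths = unlist(paths),
                 log = log, container = container_path))
}
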