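test_that("default configurations carry the study's structural constants", {
  fc <- default_paper_config("fmri")
  expect_s3_class(fc, "fmri_sim_config")
  expect_identical(fc$n_runs, 12L)
  mc <- default_paper_config("meg")
  expect_equal(mc$sfreq, 100)
  expect_identical(mc$n_trials_per_condition, 104L)
  expect_length(fc$rois, 4)
  expect_length(mc$regions, 3)
  expect_error(default_paper_config("eeg"), "fmri|meg")
})

test_that("configuration invariants are enforced", {
  expect_error(fmri_sim_config(vein_fraction = 0.5), "vein_fraction")
  expect_error(fmri_sim_config(seed = 1.5), "integer")
  expect_error(meg_sim_config(fb_lag = 0.015), "multiple")
  expect_error(meg_sim_config(fb_lag = 0.07), "1/sfreq")
  expect_error(meg_sim_config(epoch_window = c(-0.1, 0.8)), "-0.2")
  expect_error(meg_sim_config(fb_onset = c(category = 0.05, orientation = 0.25)),
               "feedforward onset")
})

test_that("laminar fMRI generation is deterministic and structured", {
  cfg <- tiny_fmri_config(seed = 5)
  a <- generate_laminar_fmri(cfg)
  b <- generate_laminar_fmri(cfg)
  expect_identical(a, b)
  tab <- a$subjects[[1]][[1]]
  # one block per condition per task per run -> 48 blocks per task
  expect_equal(sum(tab$block_info$task == "peripheral"), cfg$n_runs * 4)
  expect_equal(sum(tab$block_info$task == "foveal"), cfg$n_runs * 4)
  expect_true(all(abs(rowSums(tab$layer_fractions) - 1) < 1e-6))
  # planted vein count matches the configured fraction exactly
  expect_equal(sum(a$ground_truth$vein_mask[[1]][[1]]),
               round(nrow(tab$betas) * cfg$vein_fraction))
})

test_that("zero-signal fMRI configuration yields exactly zero betas", {
  prof <- default_info_profile(amplitude = 0)
  cfg <- tiny_fmri_config(info_profile = prof, noise_sd = 0,
                          vein_beta_shift = 0, seed = 2)
  dat <- generate_laminar_fmri(cfg)
  expect_true(all(dat$subjects[[1]][[1]]$betas == 0))
})

test_that("MEG generation is deterministic with full condition structure", {
  cfg <- tiny_meg_config(seed = 3)
  a <- generate_meg_epochs(cfg)
  b <- generate_meg_epochs(cfg)
  expect_identical(a, b)
  ep <- a$subjects[[1]]
  expect_equal(nrow(ep$trial_table), 16 * 2 * 2 * 2)
  cells <- table(ep$trial_table$category, ep$trial_table$orientation,
                 ep$trial_table$location_set)
  expect_true(all(cells == 16))
})

test_that("default MEG trial table covers 104 trials per condition cell", {
  cfg <- meg_sim_config(regions = c(evc = 6, otc = 6, ppc = 6), seed = 1)
  ep <- generate_meg_epochs(cfg)$subjects[[1]]
  expect_equal(nrow(ep$trial_table), 104 * 2 * 2 * 2)
  cells <- table(ep$trial_table$category, ep$trial_table$orientation,
                 ep$trial_table$location_set)
  expect_true(all(cells == 104))
})

test_that("planted pattern geometry has the location structure of the design", {
  gen <- generate_meg_epochs(tiny_meg_config(seed = 9))
  pats <- gen$ground_truth$patterns[[1]]
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (feat in c("category", "orientation")) {
    ff <- pats$evc[[feat]]$feedforward
    fb <- pats$evc[[feat]]$feedback
    # location-specific feedforward, location-invariant feedback
    expect_lt(abs(cosine(ff$A, ff$B)), 0.3)
    expect_lt(abs(cosine(fb, ff$A)), 1e-10)
    expect_lt(abs(cosine(fb, ff$B)), 1e-10)
    # occipitotemporal feedforward pattern is shared across location sets
    expect_equal(cosine(pats$otc[[feat]]$feedforward$A,
                        pats$otc[[feat]]$feedforward$B), 1)
  }
})

test_that("pre-stimulus samples contain noise only", {
  cfg <- tiny_meg_config(n_trials_per_condition = 64, seed = 4)
  ep <- generate_meg_epochs(cfg)$subjects[[1]]
  pre <- ep$times < min(cfg$ff_onsets$onset)
  m <- apply(ep$data[, , pre, drop = FALSE], c(2, 3), mean)
  # trial means shrink like noise_sd / sqrt(n_trials)
  expect_lt(max(abs(m)), 5 * cfg$noise_sd / sqrt(nrow(ep$trial_table)))
})

test_that("planted feedback strength couples to reaction time", {
  gen <- generate_meg_epochs(tiny_meg_config(n_trials_per_condition = 64,
                                             seed = 7))
  ep <- gen$subjects[[1]]
  r <- cor(gen$ground_truth$fb_strength[[1]], ep$trial_table$rt)
  expect_lt(r, 0)
})
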