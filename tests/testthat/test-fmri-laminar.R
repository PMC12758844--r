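test_that("EPI detrending removes exactly the linear spatial component", {
  set.seed(1)
  coords <- matrix(runif(60, -10, 10), 20, 3)
  expect_lt(max(abs(detrend_epi(5 + 2 * coords[, 1], coords))), 1e-8)
  expect_lt(max(abs(detrend_epi(rep(7, 20), coords))), 1e-8)
  # planted plane + noise: residual variance below raw variance and equal to
  # an independent least-squares oracle
  y <- 100 + 3 * coords[, 1] - 2 * coords[, 3] + rnorm(20)
  res <- detrend_epi(y, coords)
  expect_lt(var(res), var(y))
  oracle <- resid(lm(y ~ coords))
  expect_equal(res, unname(oracle), tolerance = 1e-10)
  expect_error(detrend_epi(y[1:5], coords[1:5, ]), "8 voxels")
})

test_that("two-Gaussian EM recovers planted memberships and symmetry", {
  set.seed(2)
  x <- c(rnorm(500), rnorm(50, mean = 10))
  truth <- rep(1:2, c(500, 50))
  fit <- fit_two_gaussian_mixture(x)
  hard <- max.col(fit$responsibilities)
  expect_gte(mean(hard == truth), 0.99)
  expect_true(abs(fit$means[2] - 10) < 0.5)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(rowSums(fit$responsibilities) - 1 < 1e-12))
  # negating the sample negates the means and keeps the SDs
  fneg <- fit_two_gaussian_mixture(-x)
  expect_equal(sort(fneg$means), sort(-fit$means), tolerance = 1e-4)
  expect_equal(sort(fneg$sds), sort(fit$sds), tolerance = 1e-4)
  expect_error(fit_two_gaussian_mixture(rnorm(10)), "20")
  expect_error(fit_two_gaussian_mixture(rep(1, 30)), "degenerate")
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  set.seed(3)
  x <- c(rnorm(400, 0, 1), rnorm(100, 6, 1.5))
  fit <- fit_two_gaussian_mixture(x)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("unimodal samples stay below the bimodality separation gate", {
  seps <- vapply(1:20, function(s) {
    set.seed(s)
    fit_two_gaussian_mixture(rnorm(1000))$separation
  }, numeric(1))
  expect_true(all(seps < 2))
})

test_that("layer assignment follows dominant fractions with fixed tie rules", {
  f <- rbind(c(.05, .05, .80, .05, .05),
             c(.60, 0, .20, .10, .10),
             c(.05, .05, .45, .45, 0),
             c(0, 0, .10, .10, .80))
  colnames(f) <- c("wm", "csf", "deep", "middle", "superficial")
  expect_identical(assign_layer(f),
                   c("deep", "excluded", "deep", "superficial"))
  expect_error(assign_layer(matrix(c(-.1, .3, .3, .3, .2), 1)), "non-negative")
})

test_that("t-value voxel ranking matches a direct computation", {
  set.seed(4)
  X <- matrix(rnorm(50 * 20), 50, 20)
  labels <- rep(c("a", "b"), each = 10)
  X[7, labels == "a"] <- X[7, labels == "a"] + 10
  sel <- select_voxels_by_t(X, labels, 5)
  expect_identical(sel[1], 7L)
  # oracle: per-voxel pooled t
  tor <- apply(X, 1, function(v) t.test(v[labels == "a"], v[labels == "b"],
                                        var.equal = TRUE)$statistic)
  expect_identical(sel, order(abs(tor), decreasing = TRUE)[1:5])
  # saturation: k beyond the voxel count returns everything ranked
  expect_identical(select_voxels_by_t(X, labels, 100),
                   order(abs(tor), decreasing = TRUE))
  # shuffled labels select a different set than the signal-based ranking
  set.seed(5)
  sel_shuf <- select_voxels_by_t(X, sample(labels), 5)
  expect_false(identical(sort(sel), sort(sel_shuf)))
  expect_error(select_voxels_by_t(X, labels, 0), "k")
})

test_that("vasculature flagging recovers the planted vein mask and gates", {
  cfg <- fmri_sim_config(n_subjects = 1, rois = c(foveal_v1 = 400),
                         vein_fraction = 0.10, seed = 3)
  dat <- generate_laminar_fmri(cfg)
  tab <- dat$subjects[[1]][[1]]
  truth <- dat$ground_truth$vein_mask[[1]][[1]]
  fl <- flag_vasculature(tab)
  frac <- mean(fl$mask)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.15)
  expect_gte(sum(fl$mask & truth) / sum(truth), 0.9)
  # no veins planted and unimodal distributions: the gate suppresses all
  # exclusions
  cfg0 <- fmri_sim_config(n_subjects = 1, rois = c(foveal_v1 = 400),
                          vein_fraction = 0, seed = 4)
  tab0 <- generate_laminar_fmri(cfg0)$subjects[[1]][[1]]
  expect_equal(sum(flag_vasculature(tab0)$mask), 0)
  # veins present but with zero shifts are indistinguishable -> same result
  cfg_null <- fmri_sim_config(n_subjects = 1, rois = c(foveal_v1 = 400),
                              vein_fraction = 0.10, vein_beta_shift = 0,
                              vein_epi_shift = 0, seed = 4)
  tabn <- generate_laminar_fmri(cfg_null)$subjects[[1]][[1]]
  fln <- flag_vasculature(tabn)
  expect_equal(sum(fln$mask), 0)
})

test_that("leave-one-run-out decoding recovers the planted dissociation", {
  # feedforward-like variant: orientation information in all layers, no
  # category information
  prof <- data.frame(roi = "foveal_v1",
                     layer = c("deep", "middle", "superficial"),
                     feature = "orientation", amplitude = 3)
  cfg <- tiny_fmri_config(rois = c(foveal_v1 = 300), info_profile = prof,
                          seed = 11)
  tab <- generate_laminar_fmri(cfg)$subjects[[1]][[1]]
  vasc <- flag_vasculature(tab)
  ori <- decode_leave_one_run_out(tab, "orientation", "foveal", vasc = vasc)
  cat_ <- decode_leave_one_run_out(tab, "category", "foveal", vasc = vasc)
  expect_gt(ori$accuracy, 0.9)
  band <- 1.96 * sqrt(0.25 / (12 * 4))
  expect_lt(abs(cat_$accuracy - 0.5), 2.5 * band)
  expect_equal(ori$n_folds, 12)
  expect_equal(ori$chance, 0.5)
})

test_that("decoding is invariant to a consistent voxel permutation", {
  cfg <- tiny_fmri_config(seed = 12)
  tab <- generate_laminar_fmri(cfg)$subjects[[1]][[1]]
  acc1 <- decode_leave_one_run_out(tab, "category", "peripheral")$accuracy
  set.seed(99)
  perm <- sample(nrow(tab$betas))
  tab2 <- laminar_voxel_table(tab$betas[perm, ], tab$block_info,
                              tab$layer_fractions[perm, ],
                              tab$mean_epi[perm], tab$coords[perm, ], tab$roi)
  acc2 <- decode_leave_one_run_out(tab2, "category", "peripheral")$accuracy
  expect_equal(acc1, acc2)
})
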