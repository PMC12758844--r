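test_that("pseudo-trial partitions are balanced, disjoint and exhaustive", {
  idx <- list(a = 1:104, b = 201:304)
  parts <- make_pseudotrials(idx, 8, seed = 1)
  expect_true(all(lengths(parts$a) == 13))
  expect_setequal(unlist(parts$a), 1:104)
  expect_setequal(unlist(parts$b), 201:304)
  expect_equal(sum(duplicated(unlist(parts$a))), 0)
  # near-equal sizes when not divisible
  p2 <- make_pseudotrials(list(a = 1:10), 4, seed = 1)
  expect_lte(diff(range(lengths(p2$a))), 1)
  expect_error(make_pseudotrials(list(tiny = 1:7), 8, seed = 1), "tiny")
  # deterministic under seed
  expect_identical(parts, make_pseudotrials(idx, 8, seed = 1))
})

test_that("F-value feature ranking matches a brute-force ANOVA oracle", {
  set.seed(2)
  X <- matrix(rnorm(40 * 12), 40, 12)
  labels <- rep(c("c1", "c2", "c3", "c4"), each = 10)
  X[, 3] <- X[, 3] + rep(c(0, 1, 2, 3), each = 10)
  X[, 5] <- 1  # constant feature
  sel <- select_features_by_f(X, labels)
  oracle <- vapply(seq_len(ncol(X)), function(j) {
    if (var(X[, j]) == 0) return(0)
    summary(aov(X[, j] ~ factor(labels)))[[1]]$`F value`[1]
  }, numeric(1))
  keep <- oracle > 0
  expect_equal(sel$f[keep], oracle[keep], tolerance = 1e-10)
  expect_identical(sel$order[1], 3L)
  expect_identical(sel$order[ncol(X)], 5L)  # constant ranked last
  expect_error(select_features_by_f(X, rep("one", 40)), "2 conditions")
})

test_that("zero-amplitude epochs decode at chance", {
  amps <- default_meg_amplitudes()
  amps$amplitude <- 0
  cfg <- tiny_meg_config(n_trials_per_condition = 32, amplitudes = amps,
                         epoch_window = c(-0.2, 0), seed = 6)
  ep <- generate_meg_epochs(cfg)$subjects[[1]]
  tc <- decode_timecourse(ep, "evc", "category", "same_location",
                          n_repeats = 5, k = 6, seed = 7)
  # repeats reuse the same trials, so the binomial count is the 64 pseudo-
  # trial classifications of one partition; allow a 2x margin on its band
  band <- 1.96 * sqrt(0.25 / 64)
  expect_true(all(abs(tc$accuracy - 0.5) < 2 * band))
  expect_lt(abs(mean(tc$accuracy) - 0.5), 0.05)
})

test_that("planted feedforward signal is decodable at the right times", {
  cfg <- tiny_meg_config(n_trials_per_condition = 32,
                         regions = c(evc = 12, otc = 12, ppc = 12), seed = 8)
  ep <- generate_meg_epochs(cfg)$subjects[[1]]
  tc <- decode_timecourse(ep, "evc", "category", "same_location",
                          n_repeats = 2, k = 12, seed = 9)
  early <- tc$times >= 0.05 & tc$times <= 0.2
  expect_gt(max(tc$accuracy[early]), 0.75)
  # cross-location decoding in early visual cortex is at chance before the
  # feedback onset and rises after it
  tcx <- decode_timecourse(ep, "evc", "category", "cross_location",
                           n_repeats = 2, k = 12, seed = 9)
  pre_fb <- tcx$times > 0 & tcx$times < 0.2
  post_fb <- tcx$times >= 0.27 & tcx$times <= 0.5
  expect_lt(mean(tcx$accuracy[pre_fb]), 0.6)
  expect_gt(max(tcx$accuracy[post_fb]), 0.75)
})

test_that("Gaussian smoothing preserves DC, width, and the identity case", {
  x <- rep(3.7, 101)
  expect_equal(gaussian_smooth(x, 0.1, 100), x, tolerance = 1e-12)
  expect_identical(gaussian_smooth(x, 0, 100), x)
  # impulse response has FWHM = 2 x half-width (within one sample)
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(imp, 0.1, 100)
  above <- which(sm >= max(sm) / 2)
  fwhm_s <- (max(above) - min(above)) / 100
  expect_lte(abs(fwhm_s - 0.2), 0.01)
  # NA handling: missing points stay missing, neighbors use renormalized
  # weights
  xna <- c(1, 2, NA, 4, 5, 4, 3, 2, 1, 2, 3)
  smna <- gaussian_smooth(xna, 0.02, 100)
  expect_true(is.na(smna[3]))
  expect_false(anyNA(smna[-3]))
})

test_that("peak normalization and latency behave as the closed forms say", {
  times <- seq(-0.1, 0.5, by = 0.01)
  acc <- rep(0.5, length(times))
  ramp <- times >= 0 & times <= 0.1
  acc[ramp] <- 0.5 + 0.3 * times[ramp] / 0.1
  acc[times > 0.1] <- 0.8
  tc <- structure(list(accuracy = acc, times = times, chance = 0.5),
                  class = "decoding_timecourse")
  norm <- normalize_to_peak(tc)
  expect_equal(max(norm), 1)
  # scaling the above-chance part leaves the normalized curve unchanged
  tc2 <- tc
  tc2$accuracy <- 0.5 + 2 * (acc - 0.5)
  expect_equal(normalize_to_peak(tc2), norm, tolerance = 1e-12)
  lat <- latency_to_fraction(tc, 0.75)
  expect_true(lat$valid)
  expect_equal(lat$time, 0.075, tolerance = 1e-12)
  # flat series: no above-chance peak
  flat <- structure(list(accuracy = rep(0.5, length(times)), times = times,
                         chance = 0.5), class = "decoding_timecourse")
  expect_error(normalize_to_peak(flat), "peak")
  expect_false(latency_to_fraction(flat)$valid)
})

test_that("repeat averaging reduces the variance of the accuracy estimate", {
  cfg <- tiny_meg_config(n_trials_per_condition = 16, seed = 10)
  ep <- generate_meg_epochs(cfg)$subjects[[1]]
  ti <- which.min(abs(ep$times - 0.15))
  ep1 <- epoch_set(ep$data[, , ti, drop = FALSE], ep$times[ti], ep$sfreq,
                   ep$trial_table, ep$feature_region)
  acc_of <- function(n_rep, s) decode_timecourse(ep1, "evc", "category",
                                                 "same_location",
                                                 n_repeats = n_rep, k = 6,
                                                 seed = s)$accuracy[1]
  a1 <- vapply(1:12, function(s) acc_of(1, 100 + s), numeric(1))
  a20 <- vapply(1:12, function(s) acc_of(20, 200 + s), numeric(1))
  expect_lt(var(a20), var(a1))
})
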