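test_that("hyperplane distances match the explicit geometric computation", {
  toy <- toy_margin_set()
  fit <- laminarflow:::fit_linear_svm(toy$x, toy$y, cost = 1)
  # brute-force oracle: (w.x + b) / |w| computed longhand
  oracle <- (toy$x %*% fit$w + fit$b) / sqrt(sum(fit$w^2))
  d <- laminarflow:::svm_decision(fit, toy$x) / fit$w_norm
  expect_equal(d, drop(oracle), tolerance = 1e-10)
  # on this symmetric set the max-margin hyperplane is x1 = 0, so the
  # geometric distance of each point is its first coordinate
  signed <- d * ifelse(toy$y == fit$positive_class, 1, -1)
  expect_equal(abs(d), abs(toy$x[, 1]), tolerance = 1e-2)
  expect_true(all(signed > 0))
  # a point exactly on the hyperplane has distance 0
  on_plane <- matrix(c(0, 2), 1)
  expect_equal(laminarflow:::svm_decision(fit, on_plane) / fit$w_norm, 0,
               tolerance = 1e-6)
})

test_that("strength time courses are near zero without planted signal", {
  amps <- default_meg_amplitudes()
  amps$amplitude <- 0
  cfg <- tiny_meg_config(n_trials_per_condition = 32, amplitudes = amps,
                         epoch_window = c(-0.2, 0), seed = 12)
  ep <- generate_meg_epochs(cfg)$subjects[[1]]
  st <- strength_timecourse(ep, "evc", "category", "cross_location", k = 6,
                            seed = 13)
  m <- colMeans(st$distance)
  sem <- apply(st$distance, 2, sd) / sqrt(nrow(st$distance))
  expect_true(all(abs(m) < 3 * sem + 1e-12))
})

test_that("strength normalization is an idempotent per-time z-score", {
  set.seed(14)
  st <- strength_from_matrix(matrix(rnorm(200), 20), seq(0, 9) / 100, "x")
  n1 <- normalize_strength(st)
  expect_lt(max(abs(colMeans(n1$distance))), 1e-8)
  expect_lt(max(abs(apply(n1$distance, 2, sd) - 1)), 1e-8)
  n2 <- normalize_strength(n1)
  expect_equal(n1$distance, n2$distance, tolerance = 1e-8)
  # per-column affine transforms of the input do not change the output
  st2 <- st
  st2$distance <- sweep(sweep(st$distance, 2, runif(10, 1, 3), "*"), 2,
                        runif(10, -5, 5), "+")
  n3 <- normalize_strength(st2)
  expect_equal(n3$distance, n1$distance, tolerance = 1e-8)
  stz <- st
  stz$distance[, 4] <- 2
  expect_error(normalize_strength(stz), "0.030")
})

test_that("Granger influence is non-negative and null for independent noise", {
  set.seed(15)
  times <- seq(-0.3, 0.5, by = 0.01)
  x <- matrix(rnorm(200 * length(times)), 200)
  y <- matrix(rnorm(200 * length(times)), 200)
  sts <- list(x = normalize_strength(strength_from_matrix(x, times, "x")),
              y = normalize_strength(strength_from_matrix(y, times, "y")))
  g <- conditional_granger(sts, "x", "y")
  expect_true(all(g$gc >= 0))
  expect_lt(max(g$gc), 0.02)
  expect_equal(g$gc, log(g$u_reduced / g$u_full), tolerance = 1e-12)
  # lags at 100 Hz with order 5 span exactly 10..50 ms
  expect_equal(g$lag_times, c(0.01, 0.02, 0.03, 0.04, 0.05))
})

test_that("a planted AR coupling matches the closed-form influence", {
  chk <- analytic_gc_check(n_trials = 500, beta = 0.5, lag_samples = 2,
                           seed = 16)
  expect_lt(chk$relative_error, 0.15)
  expect_gt(chk$gc_hat, chk$gc_reverse)
  expect_true(all(chk$gc_all >= 0))
  expect_true(all(chk$gc_reverse_all >= 0))
})

test_that("conditioning absorbs a relayed signal (chain simulation)", {
  # true path is x -> z -> y; conditioning on z must suppress the direct
  # x -> y influence relative to the unconditioned pair analysis
  set.seed(17)
  n <- 500
  times <- seq(-0.3, 0.5, by = 0.01)
  nt <- length(times)
  x <- matrix(rnorm(n * nt), n)
  z <- matrix(rnorm(n * nt, sd = 0.3), n)
  y <- matrix(rnorm(n * nt, sd = 0.3), n)
  z[, 2:nt] <- z[, 2:nt] + 0.8 * x[, 1:(nt - 1)]
  y[, 2:nt] <- y[, 2:nt] + 0.8 * z[, 1:(nt - 1)]
  wrap <- function(m, nm) normalize_strength(strength_from_matrix(m, times, nm))
  sts3 <- list(x = wrap(x, "x"), y = wrap(y, "y"), z = wrap(z, "z"))
  g_cond <- conditional_granger(sts3, "x", "y")
  g_pair <- conditional_granger(sts3[c("x", "y")], "x", "y")
  post <- g_cond$times > 0
  expect_lt(mean(g_cond$gc[post]), 0.1 * mean(g_pair$gc[post]))
})

test_that("baseline correction and onset detection handle the null case", {
  set.seed(18)
  times <- seq(-0.3, 0.5, by = 0.01)
  gcs <- lapply(1:6, function(s) {
    x <- matrix(rnorm(100 * length(times)), 100)
    y <- matrix(rnorm(100 * length(times)), 100)
    sts <- list(x = normalize_strength(strength_from_matrix(x, times, "x")),
                y = normalize_strength(strength_from_matrix(y, times, "y")))
    conditional_granger(sts, "x", "y")
  })
  on <- gc_baseline_and_onset(gcs, n_perm = 500, seed = 19)
  expect_true(is.na(on$onset))
  expect_length(on$baselines, 6)
  expect_true(all(is.finite(on$baselines)))
})
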