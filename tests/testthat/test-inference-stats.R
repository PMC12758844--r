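test_that("one-sample t matches the textbook formula and edge cases", {
  x <- c(0.52, 0.55, 0.49, 0.61, 0.58, 0.47, 0.53, 0.56, 0.60, 0.51)
  res <- one_sample_t(x, mu = 0.5, tail = "one")
  t_oracle <- (mean(x) - 0.5) / (sd(x) / sqrt(10))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, pt(t_oracle, 9, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$df, 9)
  # exact symmetric sample: t = 0, two-tailed p = 1
  sym <- one_sample_t(c(-1, -1, 1, 1) + 2, mu = 2, tail = "two")
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(one_sample_t(rep(0.5, 6), mu = 0.5), "variance")
  expect_error(one_sample_t(c(1, 2), mu = 0), "3")
})

test_that("BH correction reproduces the hand-computed table and properties", {
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), m = 4)
  expect_equal(res$q, c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_identical(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  # uniform p-values collapse to q = c when m equals their number
  expect_equal(fdr_bh(rep(0.03, 5))$q, rep(0.03, 5))
  # q never below p for a single test, order preserved
  set.seed(24)
  p <- runif(20)
  q <- fdr_bh(p)$q
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # q preserves the p order
  # correcting a subset against a larger stated family is never more liberal
  p12 <- runif(12)
  expect_true(all(fdr_bh(p12, m = 24)$q >= fdr_bh(p12, m = 12)$q - 1e-12))
  expect_error(fdr_bh(p12, m = 6), "m")
})

test_that("cluster permutation handles null, strong, and planted effects", {
  # all-zero effects: no clusters at all
  cl0 <- cluster_permutation(matrix(0, 8, 30), n_perm = 200,
                             cluster_forming_p = 0.05, corrected_p = 0.05,
                             seed = 1)
  expect_equal(nrow(cl0$clusters), 0)
  # an astronomically strong sustained effect reaches the permutation floor
  set.seed(25)
  E <- matrix(rnorm(15 * 50), 15, 50)
  E[, 20:30] <- E[, 20:30] + 10
  cl <- cluster_permutation(E, n_perm = 2000, cluster_forming_p = 0.01,
                            corrected_p = 0.01, seed = 2)
  sig <- cl$clusters[cl$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  # approaches the permutation floor; an identity sign-flip drawn among the
  # random permutations can add at most one tie
  expect_gte(min(sig$p_corrected), 1 / 2001 - 1e-12)
  expect_lte(min(sig$p_corrected), 2 / 2001 + 1e-12)
  expect_error(cluster_permutation(E, n_perm = 50), "insufficient")
  expect_error(cluster_permutation(E[1:3, ], n_perm = 200), "5 subjects")
})

test_that("a planted 1-SD effect over 100 ms is localized correctly", {
  hits <- vapply(1:5, function(r) {
    set.seed(100 + r)
    E <- matrix(rnorm(15 * 100), 15, 100)
    span <- 41:50
    E[, span] <- E[, span] + 1
    cl <- cluster_permutation(E, n_perm = 1000, cluster_forming_p = 0.05,
                              corrected_p = 0.05, seed = r,
                              times = seq(0.01, 1, by = 0.01))
    sig <- cl$clusters[cl$clusters$significant, , drop = FALSE]
    if (!nrow(sig)) return(FALSE)
    overlap <- max(mapply(function(a, b) {
      length(intersect(a:b, span)) / length(span)
    }, sig$i_start, sig$i_end))
    overlap >= 0.8
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("permutation p-values are invariant to time reversal", {
  set.seed(26)
  E <- matrix(rnorm(10 * 40), 10, 40)
  E[, 10:18] <- E[, 10:18] + 0.8
  a <- cluster_permutation(E, n_perm = 500, cluster_forming_p = 0.05,
                           corrected_p = 0.05, seed = 3)
  b <- cluster_permutation(E[, 40:1], n_perm = 500, cluster_forming_p = 0.05,
                           corrected_p = 0.05, seed = 3)
  expect_equal(sort(a$clusters$p_corrected), sort(b$clusters$p_corrected),
               tolerance = 1e-12)
  expect_equal(sort(a$clusters$mass), sort(b$clusters$mass), tolerance = 1e-12)
})
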