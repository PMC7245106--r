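test_that("temporal distances obey their contract", {
  TD <- temporal_distances(c(0, 0.5, 2))
  expect_equal(sort(TD[upper.tri(TD)]), c(0.5, 1.5, 2))
  expect_equal(unclass(TD), t(unclass(TD)))
  expect_true(all(diag(TD) == 0))

  expect_equal(temporal_distances(c(0, 5))[1, 2], 5)
  expect_error(temporal_distances(c(3, 1, 2)), "sorted")
  expect_error(temporal_distances(c(1, 2, 3)), "days since")
  expect_warning(temporal_distances(c(0, 1, 1, 2)), "Duplicate")
})

test_that("the Mantel test is exact in rank-preserving and exhaustive cases", {
  times <- c(0, 0.7, 1.9, 3.2, 4.1, 6)
  TD <- temporal_distances(times)
  D <- unclass(TD)^1.7 # strictly increasing transform
  m <- mantel_spearman(D, TD, mode = "sampled", n_perm = 200, seed = 1)
  expect_equal(m$rho, 1)

  # S = 4 exhaustive mode reproduces the full 24-permutation enumeration
  t4 <- c(0, 1, 2.5, 5)
  TD4 <- temporal_distances(t4)
  D4 <- unclass(TD4)
  m4 <- mantel_spearman(D4, TD4, mode = "exhaustive")
  expect_equal(m4$n_perm, 24)
  perms <- rbind(
    expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  )
  perms <- as.matrix(perms[apply(perms, 1, function(p) length(unique(p)) == 4), ])
  ut <- upper.tri(TD4)
  obs <- cor(rank(D4[ut]), rank(unclass(TD4)[ut]))
  rhos <- apply(perms, 1, function(p) {
    cor(rank(D4[ut]), rank(unclass(TD4)[p, p][ut]))
  })
  expect_equal(m4$p, mean(rhos >= obs - 1e-12))

  # plus-one estimator
  m4b <- mantel_spearman(D4, TD4, mode = "exhaustive", estimator = "plus_one")
  expect_equal(m4b$p, (sum(rhos >= obs - 1e-12) + 1) / 25)

  expect_error(mantel_spearman(D4[1:3, 1:3], TD4[1:3, 1:3]), "at least 4")
  expect_warning(m_const <- mantel_spearman(matrix(1, 4, 4) - diag(4) * 0,
                                            TD4), "undefined")
  expect_true(m_const$degenerate)
})

test_that("the Mantel statistic agrees with an independent implementation", {
  coh <- linear_cohort(seed = 11, n = 9)
  D <- dissimilarity_matrix(coh$seizures)
  TD <- temporal_distances(coh$times)
  ours <- mantel_spearman(D, TD, n_perm = 999, seed = 5, mode = "sampled")
  ref <- vegan::mantel(as.dist(unclass(D)), as.dist(unclass(TD)),
                       method = "spearman", permutations = 999)
  expect_equal(ours$rho, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("the Mantel p-value is invariant to a common relabeling", {
  coh <- linear_cohort(seed = 3, n = 9)
  D <- dissimilarity_matrix(coh$seizures)
  TD <- temporal_distances(coh$times)
  m1 <- mantel_spearman(D, TD, n_perm = 500, seed = 7, mode = "sampled")
  perm <- withr::with_seed(8, sample(9))
  m2 <- mantel_spearman(unclass(D)[perm, perm], unclass(TD)[perm, perm],
                        n_perm = 500, seed = 7, mode = "sampled")
  expect_equal(m1$rho, m2$rho, tolerance = 1e-12)
  expect_lt(abs(m1$p - m2$p), 0.03)
})

test_that("BH-FDR follows the hand-computed step-up adjustment", {
  expect_equal(bh_fdr(0.01)$p_adjusted, 0.01)
  res <- bh_fdr(c(0.01, 0.02, 0.03))
  expect_equal(res$p_adjusted, c(0.03, 0.03, 0.03))
  expect_true(all(res$significant))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_error(bh_fdr(numeric(0)), "No p-values")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("temporal correlation patterns mask sparse or stale timescales", {
  # exact masking: 4 seizures -> 6 pairs, never reaches 7
  t4 <- c(0, 0.4, 1.1, 2)
  TD4 <- temporal_distances(t4)
  D4 <- unclass(TD4) + 0.1
  expect_warning(tcp4 <- compute_tcp(D4, TD4), "empty")
  expect_false(any(tcp4$valid))

  # threshold rule: a timescale with 6 pairs is masked, with 7 is usable
  times <- c(0, 0.1, 0.2, 0.3, 2, 2.1, 2.2)
  TD <- temporal_distances(times)
  D <- simulate_dissimilarity(times, 1, 0, 0)
  tcp <- compute_tcp(D, TD, step = 0.25, min_pairs = 7)
  idx025 <- which(abs(tcp$timescale - 0.25) < 1e-9)
  expect_equal(tcp$n_pairs[idx025], 8)
  expect_true(tcp$valid[idx025])
  # plateau masking: between 0.5 and 1.75 no new pairs arrive
  plateau <- tcp$timescale > 0.5 & tcp$timescale < 1.75
  expect_true(all(!tcp$valid[plateau]))
  expect_true(all(tcp$new_pairs[plateau] == 0))
})

test_that("the final valid timescale reproduces the global Mantel correlation", {
  coh <- linear_cohort(seed = 9, n = 10)
  D <- dissimilarity_matrix(coh$seizures)
  TD <- temporal_distances(coh$times)
  tcp <- compute_tcp(D, TD)
  m <- mantel_spearman(D, TD, n_perm = 100, seed = 1, mode = "sampled")
  last_valid <- max(which(tcp$valid))
  expect_equal(tcp$rho[last_valid], m$rho, tolerance = 1e-12)
  expect_equal(tcp$n_pairs[last_valid], choose(10, 2))
})
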