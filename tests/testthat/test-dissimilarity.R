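test_that("warping is exact in the degenerate cases", {
  A <- random_cts(6, 5, seed = 1)
  expect_equal(seizure_dissimilarity(A, A), 0)
  w <- dtw_l1(A, A)
  expect_equal(w$path$a, 1:5)
  expect_equal(w$path$b, 1:5)

  # duplicated windows cost nothing (speed invariance)
  Adup <- connectivity_ts(unclass(A)[, rep(1:5, each = 2)], attr(A, "band_index"))
  expect_equal(seizure_dissimilarity(A, Adup), 0)

  # single-window A: forced path over all windows of B
  B <- random_cts(6, 4, seed = 2)
  A1 <- connectivity_ts(unclass(A)[, 1, drop = FALSE], attr(A, "band_index"))
  w1 <- dtw_l1(A1, B)
  expect_equal(w1$path$b, 1:4)
  expect_equal(w1$total_cost, sum(colSums(abs(unclass(B) - unclass(A)[, 1]))))

  expect_error(dtw_l1(A, random_cts(5, 4, seed = 3)), "Feature dimensions")
})

test_that("DTW agrees exactly with exhaustive path enumeration for small m", {
  cases <- expand.grid(ma = c(2, 3, 5, 6), mb = c(2, 4, 6))
  for (i in seq_len(nrow(cases))) {
    A <- random_cts(4, cases$ma[i], seed = 10 + i)
    B <- random_cts(4, cases$mb[i], seed = 50 + i)
    oracle <- oracle_dtw(A, B)
    w <- dtw_l1(A, B)
    expect_equal(w$total_cost, oracle$total, tolerance = 1e-12)
    expect_true(any(abs(oracle$optimal_lengths - w$K) < 0.5))
    expect_equal(seizure_dissimilarity(A, B), w$total_cost / w$K)
  }
})

test_that("constant pathways give the plain L1 distance and the support bound gives 12", {
  u_raw <- withr::with_seed(4, runif(30))
  v_raw <- withr::with_seed(5, runif(30))
  U <- make_cts(matrix(u_raw, 30, 3))
  V <- make_cts(matrix(v_raw, 30, 5))
  expect_equal(seizure_dissimilarity(U, V),
               sum(abs(unclass(U)[, 1] - unclass(V)[, 1])), tolerance = 1e-12)

  # disjoint supports in every band: L1 distance of 2 per band, 12 total
  a <- rep(c(1, 1, 0, 0), 6)
  b <- rep(c(0, 0, 1, 1), 6)
  A <- make_cts(matrix(a, 24, 1))
  B <- make_cts(matrix(b, 24, 1))
  expect_equal(seizure_dissimilarity(A, B), 12)
})

test_that("the dissimilarity matrix is symmetric, consistent under permutation", {
  sz <- lapply(1:3, function(i) random_cts(5, 4, seed = 100))
  D0 <- dissimilarity_matrix(sz)
  expect_true(all(D0 == 0)) # identical seizures

  sz <- lapply(1:4, function(i) random_cts(5, 3 + i, seed = 200 + i))
  D <- dissimilarity_matrix(sz, ids = letters[1:4])
  expect_equal(unclass(D), t(unclass(D)))
  expect_true(all(diag(D) == 0))
  perm <- c(3, 1, 4, 2)
  Dp <- dissimilarity_matrix(sz[perm], ids = letters[perm])
  expect_equal(unclass(Dp), unclass(D)[perm, perm])

  expect_error(dissimilarity_matrix(list(sz[[1]], random_cts(4, 3, seed = 1))),
               "Mixed feature")
})

test_that("band contributions decompose the dissimilarity", {
  A <- random_cts(5, 4, seed = 7)
  B <- random_cts(5, 6, seed = 8)
  bc <- band_contributions(A, B)
  expect_true(all(bc$contribution >= 0))
  expect_equal(sum(bc$contribution), seizure_dissimilarity(A, B),
               tolerance = 1e-9)

  # identical seizures: all contributions zero
  expect_true(all(band_contributions(A, A)$contribution == 0))

  # difference confined to the delta block
  base <- withr::with_seed(9, matrix(runif(30 * 4), 30, 4))
  other <- base
  other[1:5, ] <- base[1:5, c(2, 1, 4, 3)]
  A2 <- make_cts(base)
  B2 <- make_cts(other)
  bc2 <- band_contributions(A2, B2)
  expect_true(all(bc2$contribution[-1] == 0))
  expect_gt(bc2$contribution[1], 0)
})

test_that("Sammon projection embeds exact configurations and preserves rank order", {
  # three points whose L1 distances form a Euclidean-embeddable triangle
  X <- cbind(c(0, 0), c(3, 0), c(0, 4))
  proj <- mds_project(X, seed = 1)
  expect_lt(attr(proj, "stress"), 1e-6)
  d_out <- as.matrix(dist(cbind(proj$dim1, proj$dim2)))
  d_in <- as.matrix(dist(t(X), method = "manhattan"))
  expect_equal(d_out[upper.tri(d_out)], d_in[upper.tri(d_in)], tolerance = 1e-3)

  # all identical points collapse without blow-up
  same <- matrix(1, 4, 5)
  proj_same <- mds_project(same)
  expect_true(all(proj_same$dim1 == proj_same$dim1[1]))
  expect_equal(attr(proj_same, "stress"), 0)

  # rank-order preservation on a 50-window synthetic pathway
  skel <- pathway_skeleton(50, 10, seed = 12)
  cts <- connectivity_ts(skel$A, skel$band_index)
  proj50 <- mds_project(cts, seed = 2)
  d_out <- dist(cbind(proj50$dim1, proj50$dim2))
  d_in <- dist(t(unclass(cts)), method = "manhattan")
  expect_gt(cor(as.vector(d_out), as.vector(d_in), method = "spearman"), 0.9)
})

test_that("gap-statistic clustering finds planted groups and calls noise a spectrum", {
  # two tight, well-separated pathway groups
  withr::with_seed(13, {
    g1 <- matrix(rnorm(2 * 6, mean = 0, sd = 0.1), ncol = 6)
    g2 <- matrix(rnorm(2 * 6, mean = 5, sd = 0.1), ncol = 6)
  })
  pts <- cbind(g1, g2)
  D <- as.matrix(dist(t(pts)))
  dimnames(D) <- list(sprintf("s%02d", 1:12), sprintf("s%02d", 1:12))
  cl <- cluster_pathways(structure(D, class = c("ictal_dissim", "matrix", "array")),
                         max_k = 5, n_ref = 50, seed = 1)
  expect_equal(cl$k, 2)
  expect_length(unique(cl$assignments[1:6]), 1)
  expect_length(unique(cl$assignments[7:12]), 1)
  expect_false(cl$assignments[1] == cl$assignments[7])
  expect_length(cl$assignments, 12)

  # uniform random dissimilarities: k = 1 in the majority of seeded runs
  ks <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      M <- matrix(0, 10, 10)
      M[upper.tri(M)] <- runif(45)
      M <- M + t(M)
    })
    cluster_pathways(M, max_k = 4, n_ref = 50, seed = s)$k
  }, numeric(1))
  expect_gt(mean(ks == 1), 0.5)

  expect_error(cluster_pathways(matrix(0, 2, 2)), "at least 3")
})
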