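# Fixtures are generated in code; nothing is read from disk.

# Build a connectivity time series from raw nonnegative features by
# renormalizing each band block.
make_cts <- function(raw, n_bands = 6L, id = NULL) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) %% n_bands == 0)
  bi <- band_block_index(nrow(raw) / n_bands, n_bands)
  feats <- raw / rowsum(raw, bi)[bi, , drop = FALSE]
  connectivity_ts(feats, bi, seizure_id = id)
}

random_cts <- function(n_edges, m, n_bands = 6L, seed = 1L, id = NULL) {
  withr::with_seed(seed, {
    make_cts(matrix(stats::runif(n_edges * n_bands * m), n_edges * n_bands, m),
             n_bands = n_bands, id = id)
  })
}

# Exhaustive enumeration of all admissible DTW paths (steps (1,0), (0,1),
# (1,1), fixed endpoints). Returns a list of K x 2 index matrices.
enumerate_warp_paths <- function(m_a, m_b) {
  out <- list()
  walk <- function(a, b, path) {
    path <- rbind(path, c(a, b))
    if (a == m_a && b == m_b) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    if (a < m_a) walk(a + 1, b, path)
    if (b < m_b) walk(a, b + 1, path)
    if (a < m_a && b < m_b) walk(a + 1, b + 1, path)
  }
  walk(1, 1, matrix(numeric(0), 0, 2))
  out
}

# Brute-force DTW: minimum total L1 cost over all admissible paths, plus the
# per-path mean for every optimal path.
oracle_dtw <- function(A, B) {
  A <- as.matrix(unclass(A))
  B <- as.matrix(unclass(B))
  cost <- matrix(0, ncol(A), ncol(B))
  for (a in seq_len(ncol(A))) cost[a, ] <- colSums(abs(B - A[, a]))
  paths <- enumerate_warp_paths(ncol(A), ncol(B))
  totals <- vapply(paths, function(p) sum(cost[p]), numeric(1))
  best <- which(abs(totals - min(totals)) < 1e-9)
  list(
    total = min(totals),
    optimal_means = vapply(best, function(i) totals[i] / nrow(paths[[i]]), numeric(1)),
    optimal_lengths = vapply(best, function(i) nrow(paths[[i]]), numeric(1))
  )
}

# Small drifted cohort used by several suites.
linear_cohort <- function(seed = 1L, n = 12, noise = 0.1) {
  simulate_cohort(n_seizures = n, monitoring_days = 7, l_true = 1, c_true = 0,
                  n_true = noise, seed = seed)
}
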