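test_that("seizure onset times respect the packing constraints", {
  t2 <- sample_seizure_times(2, 5, min_gap_days = 0.5, seed = 42)
  expect_identical(t2[1], 0)
  expect_gte(t2[2], 0.5)
  expect_lte(t2[2], 5)

  t6 <- sample_seizure_times(6, 5, min_gap_days = 0, seed = 1)
  expect_length(t6, 6)
  expect_identical(t6[1], 0)
  expect_false(is.unsorted(t6, strictly = TRUE))

  expect_error(sample_seizure_times(10, 1, min_gap_days = 0.2),
               "Infeasible packing")

  for (s in 1:20) {
    tt <- sample_seizure_times(8, 10, min_gap_days = 0.4, seed = s)
    expect_true(all(diff(tt) >= 0.4))
    expect_lte(max(tt), 10)
  }
})

test_that("latent drift matches its closed forms", {
  expect_equal(latent_drift(c(0, 7), 1, 0, 0), c(0, 1))
  expect_equal(latent_drift(c(0, 0.25, 0.5), 0, 1, 0), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(latent_drift(c(0, 3), 0, 0, 0), c(0, 0))
  expect_error(latent_drift(c(0, 1), -1, 0, 0), "nonnegative")
  # deterministic given seed
  expect_identical(latent_drift(c(0, 1, 2), 1, 1, 0.5, seed = 7),
                   latent_drift(c(0, 1, 2), 1, 1, 0.5, seed = 7))
})

test_that("pathway mixing reproduces endpoints and is symmetric at the midpoint", {
  skel <- pathway_skeleton(n_windows = 8, n_edges = 10, seed = 3)
  a <- synthesize_seizure_connectivity(skel, 0, within_noise_sd = 0)
  b <- synthesize_seizure_connectivity(skel, 1, within_noise_sd = 0)
  expect_equal(unclass(a), skel$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(b), skel$B, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(synthesize_seizure_connectivity(skel, 1.5), "\\[0, 1\\]")

  # constant endpoint pathways: the midpoint mixture is equidistant from both
  skc <- skel
  skc$A <- skel$A[, rep(1, 8)]
  skc$B <- skel$B[, rep(1, 8)]
  mid <- synthesize_seizure_connectivity(skc, 0.5, within_noise_sd = 0)
  da <- seizure_dissimilarity(mid, connectivity_ts(skc$A, skc$band_index))
  db <- seizure_dissimilarity(mid, connectivity_ts(skc$B, skc$band_index))
  expect_equal(da, db, tolerance = 1e-9)
})

test_that("generated cohorts satisfy the pipeline invariants and are reproducible", {
  coh <- simulate_cohort(n_seizures = 6, seed = 11, l_true = 1, c_true = 0.5,
                         n_true = 0.2)
  for (sz in coh$seizures) {
    expect_true(all(unclass(sz) >= 0))
    sums <- rowsum(unclass(sz), attr(sz, "band_index"))
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  coh2 <- simulate_cohort(n_seizures = 6, seed = 11, l_true = 1, c_true = 0.5,
                          n_true = 0.2)
  expect_identical(coh$times, coh2$times)
  expect_identical(lapply(coh$seizures, unclass), lapply(coh2$seizures, unclass))

  # monotone drift without noise
  mono <- simulate_cohort(n_seizures = 8, seed = 5, l_true = 1, c_true = 0,
                          n_true = 0, within_noise_sd = 0)
  expect_false(is.unsorted(mono$lambda))
})

test_that("synthetic iEEG respects the stated variance ratio and band limits", {
  expect_error(synthesize_ieeg(4, 200, 10, shared_band = c(80, 150)),
               "Nyquist")
  rec <- synthesize_ieeg(4, 512, 30, shared_band = c(8, 13), snr = 2, seed = 9)
  expect_s3_class(rec, "ictal_recording")
  expect_equal(dim(rec$samples), c(4, 512 * 30))
  # channel variance = source (unit) + noise (1/snr)
  v <- apply(rec$samples, 1, var)
  expect_equal(mean(v), 1 + 1 / 2, tolerance = 0.1)
})
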