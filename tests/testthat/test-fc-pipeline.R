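test_that("preprocessing re-references, filters and guards its preconditions", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  withr::with_seed(21, {
    x <- matrix(rnorm(4 * length(t)), 4)
  })
  rec <- recording(x, fs)
  out <- preprocess_recording(rec, preprocess_config(target_fs = fs))
  expect_lt(max(abs(colMeans(out$samples))), 1e-6)
  expect_equal(ncol(out$samples), ncol(x))

  # line-noise rejection on a seizure-length clip: pure 50-Hz sinusoid
  # nearly vanishes (edge ringing of the zero-phase notch is confined to the
  # clip ends)
  t60 <- seq(0, 60 - 1 / fs, by = 1 / fs)
  line <- sin(2 * pi * 50 * t60)
  rec_line <- recording(rbind(line, -line), fs)
  out_line <- preprocess_recording(rec_line, preprocess_config(target_fs = fs, line_freq = 50))
  expect_lt(sqrt(mean(out_line$samples[1, ]^2)) / sqrt(mean(line^2)), 0.05)
  interior <- round(length(t60) / 4):round(3 * length(t60) / 4)
  expect_lt(sqrt(mean(out_line$samples[1, interior]^2)) / sqrt(mean(line^2)), 1e-4)

  # sub-bandpass drift is attenuated
  slow <- sin(2 * pi * 0.1 * t)
  rec_slow <- recording(rbind(slow, -slow), fs)
  out_slow <- preprocess_recording(rec_slow, preprocess_config(target_fs = fs))
  expect_lt(sqrt(mean(out_slow$samples[1, ]^2)) / sqrt(mean(slow^2)), 0.10)

  # gap handling
  mask <- matrix(FALSE, 2, length(t))
  mask[1, 100:140] <- TRUE # 0.08 s > 0.05 s
  rec_gap <- recording(rbind(slow, slow), fs, missing_mask = mask)
  expect_error(preprocess_recording(rec_gap, preprocess_config(target_fs = fs)),
               "gap")
  cfg_loose <- preprocess_config(target_fs = fs, max_gap_s = 0.1)
  expect_no_error(preprocess_recording(rec_gap, cfg_loose))

  # sampling rate too low for the 150-Hz edge
  expect_error(preprocess_config(target_fs = 256), "bandpass")
  rec_lofs <- recording(matrix(rnorm(2 * 400), 2), fs = 250)
  expect_error(preprocess_recording(rec_lofs, preprocess_config(target_fs = 512)),
               "150")
})

test_that("band coherence is exact for identical channels and biased-bounded for noise", {
  fs <- 512
  withr::with_seed(31, {
    base <- rnorm(10 * fs)
    x <- rbind(base, 2.5 * base, rnorm(10 * fs))
  })
  arr <- band_coherence_window(x, fs)
  expect_equal(dim(arr), c(3, 3, 6))
  expect_true(all(arr >= 0 & arr <= 1))
  for (b in 1:6) {
    expect_equal(unname(arr[1, 2, b]), 1, tolerance = 1e-6) # copy up to scale
    expect_equal(arr[, , b], t(arr[, , b]))
  }

  # independent white noise: finite-sample bias stays below 0.35
  vals <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      w <- matrix(rnorm(2 * 10 * fs), 2)
    })
    mean(band_coherence_window(w, fs)[1, 2, ])
  }, numeric(1))
  expect_lt(mean(vals), 0.35)

  expect_error(band_coherence_window(rbind(base, rep(1, 10 * fs)), fs),
               "zero variance")
})

test_that("vectorization uses row-major upper-triangle order and L1-normalizes per band", {
  n <- 4
  mats <- array(0, c(n, n, 6))
  # distinct, recognisable entries in band 1
  m1 <- matrix(0, n, n)
  m1[upper.tri(m1)] <- 0 # fill row-major below
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) { k <- k + 1; m1[i, j] <- k; m1[j, i] <- k }
  mats[, , 1] <- m1
  for (b in 2:6) mats[, , b] <- matrix(1, n, n)
  v <- vectorize_normalize(mats)
  expect_length(v, 36)
  # band 1 comes out in the order 1..6 (row-major) before normalization
  expect_equal(v[1:6], (1:6) / sum(1:6))
  # uniform bands normalize to 1/6
  expect_equal(unname(v[7:12]), rep(1 / 6, 6))
  # scale invariance
  expect_equal(vectorize_normalize(mats * 2), v)
  # all-zero band errors
  mats[, , 3] <- 0
  expect_error(vectorize_normalize(mats), "all zero")
})

test_that("window counts follow floor(duration - 10) + 1 and short seizures are rejected", {
  fs <- 512
  mk <- function(dur_s, seed) {
    withr::with_seed(seed, recording(matrix(rnorm(3 * dur_s * fs), 3), fs))
  }
  cts30 <- seizure_connectivity(mk(30, 1))
  expect_equal(ncol(cts30), 21)
  cts10 <- seizure_connectivity(mk(10, 2))
  expect_equal(ncol(cts10), 1)
  expect_error(seizure_connectivity(mk(8, 3)), "shorter than")

  V <- assemble_cohort_matrix(list(seizure_connectivity(mk(12, 4)),
                                   seizure_connectivity(mk(15, 5))))
  expect_equal(ncol(V$V), 3 + 6)
  expect_equal(nrow(V$windows), 9)

  # determinism: identical recording, identical features
  expect_identical(unclass(seizure_connectivity(mk(12, 4))),
                   unclass(seizure_connectivity(mk(12, 4))))
})

test_that("coherence estimate approaches the analytic value as the clip grows", {
  est <- function(duration_s, seed) {
    rec <- synthesize_ieeg(3, 512, duration_s, shared_band = c(8, 13),
                           snr = 1, seed = seed)
    n_win <- floor(duration_s - 10) + 1
    vals <- vapply(seq(1, n_win, by = 5), function(w) {
      s0 <- (w - 1) * 512 + 1
      arr <- band_coherence_window(rec$samples[, s0:(s0 + 10 * 512 - 1)], 512)
      mean(arr[, , "alpha"][upper.tri(arr[, , 1])])
    }, numeric(1))
    mean(vals)
  }
  short <- est(60, seed = 8)
  long <- est(300, seed = 8)
  expect_lt(abs(long - 0.25), abs(short - 0.25) + 0.02)
  expect_lt(abs(long - 0.25), 0.04)
})
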