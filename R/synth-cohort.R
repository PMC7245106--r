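# Synthetic seizure cohorts with planted pathway drift.
#
# Every downstream stage (dissimilarity, temporal statistics, model
# classification) can be verified against the drift parameters planted here,
# because the generated connectivity obeys exactly the invariants the real
# pipeline enforces: nonnegative features, per-band block sums of 1.

#' Sample irregular seizure onset times
#'
#' Draws `n_seizures` onset times over a monitoring window, uniformly at
#' random subject to a minimum inter-seizure gap, and shifts them so the
#' first seizure occurs at time 0. Emulates the irregular seizure timing of a
#' presurgical monitoring stay.
#'
#' @param n_seizures Number of seizures (>= 2).
#' @param monitoring_days Length of the monitoring window in days.
#' @param min_gap_days Minimum gap between consecutive seizures in days.
#' @param seed Integer seed.
#' @return Sorted numeric vector of onset times in fractional days since the
#'   first seizure; `times[1] == 0`, consecutive gaps `>= min_gap_days`,
#'   `max(times) <= monitoring_days`.
#' @export
#' @examples
#' sample_seizure_times(6, 5, min_gap_days = 0.2, seed = 1)
sample_seizure_times <- function(n_seizures, monitoring_days,
                                 min_gap_days = 0, seed = 1L) {
  if (n_seizures < 2) rlang::abort("Need at least 2 seizures.")
  if (monitoring_days <= 0) rlang::abort("`monitoring_days` must be positive.")
  if (min_gap_days < 0) rlang::abort("`min_gap_days` must be nonnegative.")
  if (n_seizures * min_gap_days > monitoring_days) {
    rlang::abort(sprintf(
      "Infeasible packing: %d seizures with a %.3g-day minimum gap do not fit in %.3g days.",
      n_seizures, min_gap_days, monitoring_days
    ))
  }
  slack <- monitoring_days - (n_seizures - 1) * min_gap_days
  times <- withr::with_seed(seed, {
    # Uniform order statistics on the slack, plus the mandatory gaps: exactly
    # the law of a uniform draw conditioned on all gaps >= min_gap_days.
    y <- sort(stats::runif(n_seizures, 0, slack))
    y + (seq_len(n_seizures) - 1) * min_gap_days
  })
  times - times[1]
}

#' Latent pathway drift at given seizure times
#'
#' Evaluates the planted drift signal
#' `g(t) = l * t / 7 + c * sin(2 * pi * t) + n * eps`, with `eps ~ N(0, 1)`
#' drawn once per seizure: a linear trend with slope one per week, a 1-day
#' sinusoid, and Gaussian noise.
#'
#' @param times Sorted seizure onset times in days.
#' @param l_true,c_true,n_true Nonnegative weights of the linear, circadian
#'   and noise components.
#' @param seed Integer seed for the noise draws.
#' @return Numeric vector, one latent scalar per seizure.
#' @export
latent_drift <- function(times, l_true, c_true, n_true, seed = 1L) {
  if (is.unsorted(times)) rlang::abort("`times` must be sorted.")
  if (l_true < 0 || c_true < 0 || n_true < 0) {
    rlang::abort("Drift weights must be nonnegative.")
  }
  eps <- if (n_true > 0) {
    withr::with_seed(seed, stats::rnorm(length(times)))
  } else {
    numeric(length(times))
  }
  l_true * times / 7 + c_true * sin(2 * pi * times) + n_true * eps
}

#' Generate a random pathway skeleton
#'
#' A skeleton holds two endpoint pathways A and B: sequences of per-window
#' feature vectors, each nonnegative with every band block summing to 1.
#' Seizures are synthesized as mixtures along the A--B segment, emulating a
#' spectrum of seizure pathways rather than discrete types. Endpoints are
#' smooth in time (random walk in log-space) so consecutive windows resemble
#' each other, as real ictal networks do.
#'
#' @param n_windows Number of time windows per endpoint pathway.
#' @param n_edges Number of channel-pair edges per band.
#' @param n_bands Number of bands (default 6).
#' @param seed Integer seed.
#' @param separation Log-scale spread separating the two endpoints; larger
#'   values make A and B more distinct.
#' @return A list of class `ictal_skeleton` with elements `A`, `B`
#'   (feature-by-window matrices), `band_index`, `n_windows`.
#' @export
pathway_skeleton <- function(n_windows, n_edges, n_bands = 6L, seed = 1L,
                             separation = 2) {
  stopifnot(n_windows >= 2, n_edges >= 1)
  bi <- band_block_index(n_edges, n_bands)
  p <- n_edges * n_bands
  make_endpoint <- function() {
    base <- stats::rnorm(p, sd = separation)
    steps <- matrix(stats::rnorm(p * n_windows, sd = 0.3), p, n_windows)
    logw <- base + t(apply(steps, 1, cumsum))
    renormalize_blocks(exp(logw), bi)
  }
  withr::with_seed(seed, {
    structure(
      list(A = make_endpoint(), B = make_endpoint(),
           band_index = bi, n_windows = n_windows),
      class = "ictal_skeleton"
    )
  })
}

#' Synthesize one seizure's connectivity time course
#'
#' Mixes the two endpoint pathways of a skeleton window by window,
#' `(1 - lambda) * A_k + lambda * B_k`, adds folded (absolute-value) Gaussian
#' noise to preserve nonnegativity, and renormalizes each band block to sum 1.
#'
#' @param skeleton An `ictal_skeleton`.
#' @param mix_lambda Mixing weight in \[0, 1\]; callers squash latent drift
#'   through a logistic to obtain it.
#' @param within_noise_sd SD of the folded Gaussian noise added per feature.
#' @param n_windows Optional number of windows (default: skeleton length);
#'   when it differs, the skeleton pathway is linearly resampled in time,
#'   emulating a faster or slower traversal of the same pathway.
#' @param seed Integer seed.
#' @param seizure_id Optional identifier.
#' @return An `ictal_cts`.
#' @export
synthesize_seizure_connectivity <- function(skeleton, mix_lambda,
                                            within_noise_sd = 0, n_windows = NULL,
                                            seed = 1L, seizure_id = NULL) {
  if (mix_lambda < 0 || mix_lambda > 1) {
    rlang::abort("`mix_lambda` must lie in [0, 1].")
  }
  A <- skeleton$A
  B <- skeleton$B
  if (!all(dim(A) == dim(B))) rlang::abort("Skeleton endpoints have mismatched dimensions.")
  if (is.null(n_windows)) n_windows <- skeleton$n_windows
  if (n_windows != skeleton$n_windows) {
    # resample the pathway in time (piecewise-linear), then renormalize
    src <- seq(0, 1, length.out = skeleton$n_windows)
    dst <- seq(0, 1, length.out = n_windows)
    A <- t(apply(A, 1, function(r) stats::approx(src, r, xout = dst)$y))
    B <- t(apply(B, 1, function(r) stats::approx(src, r, xout = dst)$y))
  }
  mix <- (1 - mix_lambda) * A + mix_lambda * B
  if (within_noise_sd > 0) {
    noise <- withr::with_seed(
      seed,
      matrix(abs(stats::rnorm(length(mix), sd = within_noise_sd)), nrow(mix))
    )
    mix <- mix + noise
  }
  feats <- renormalize_blocks(mix, skeleton$band_index)
  connectivity_ts(feats, skeleton$band_index, seizure_id = seizure_id)
}

#' Synthesize a multichannel iEEG clip with a shared band-limited source
#'
#' Every channel is the same band-limited source plus independent noise
#' filtered to the same band, at a stated source-to-noise variance ratio.
#' Because signal and noise share one spectral shape, the in-band power
#' ratio equals the variance ratio, and the analytic magnitude-squared
#' coherence between any two channels within the shared band is
#' `snr^2 / (1 + snr)^2` (0.25 at snr = 1), which makes the clip an
#' end-to-end calibration input for the coherence estimator.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz); must be at least twice the upper band edge.
#' @param duration_s Clip duration in seconds.
#' @param shared_band Numeric length-2, the source band in Hz.
#' @param snr Source-to-noise variance ratio (> 0); `Inf` gives noise-free
#'   identical channels.
#' @param seed Integer seed.
#' @return An `ictal_recording`.
#' @export
synthesize_ieeg <- function(n_channels, fs, duration_s, shared_band = c(8, 13),
                            snr = 1, seed = 1L) {
  if (shared_band[2] >= fs / 2) {
    rlang::abort("`shared_band` must lie below the Nyquist frequency.")
  }
  if (!(snr > 0)) rlang::abort("`snr` must be positive.")
  n <- round(fs * duration_s)
  withr::with_seed(seed, {
    bf <- butter_sos(4, shared_band / (fs / 2), "pass")
    band_noise <- function() {
      x <- filtfilt_sos(bf, stats::rnorm(n), round(2 * fs))
      x / stats::sd(x)
    }
    src <- band_noise()
    noise_sd <- if (is.finite(snr)) 1 / sqrt(snr) else 0
    samples <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      samples[ch, ] <- src + if (noise_sd > 0) noise_sd * band_noise() else 0
    }
    recording(samples, fs)
  })
}

#' Simulate a synthetic seizure cohort with planted drift
#'
#' Generates onset times, a latent drift signal
#' `g(t) = l * t/7 + c * sin(2 pi t) + n * eps`, squashes it through a
#' logistic `lambda = 1 / (1 + exp(-g))`, and synthesizes one connectivity
#' time course per seizure by mixing the two endpoints of a shared pathway
#' skeleton. With `n_true = 0` and `l_true > 0` the mixing weight is monotone
#' in time, so downstream dissimilarity correlates perfectly with
#' inter-seizure time at the full timescale.
#'
#' @param n_seizures Number of seizures (default 12).
#' @param monitoring_days Monitoring window length in days (default 7).
#' @param n_channels Number of emulated channels (default 6; sets the edge
#'   count `(n^2 - n) / 2` per band).
#' @param n_bands Number of bands (default 6).
#' @param windows_per_seizure Integer range (length 2) of windows per
#'   seizure, drawn uniformly (default `c(15, 30)`).
#' @param l_true,c_true,n_true Planted drift weights (default linear only).
#' @param within_noise_sd Folded-noise SD added to each seizure's features.
#' @param min_gap_days Minimum inter-seizure gap (default 0.2 d, giving the
#'   sub-day spacing needed to identify circadian structure).
#' @param squash How the latent drift is mapped to the mixing weight
#'   `lambda` in \[0, 1\]: `"affine"` (default) rescales `g` by its min-max
#'   range, which preserves the rank order of pairwise drift distances, so a
#'   noiseless linear cohort correlates perfectly with inter-seizure time at
#'   every timescale; `"logistic"` uses `1 / (1 + exp(-g))`, which
#'   compresses large drifts (rank order only approximately preserved).
#' @param center_lambda Center the latent drift at its median before the
#'   logistic squash so the cohort explores both endpoint basins (default
#'   TRUE; affine squashing is centering-invariant).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `ictal_cohort`: `seizures` (list of `ictal_cts`),
#'   `times` (days), `annotations` (tibble), `lambda`, `g`, `params`.
#' @export
simulate_cohort <- function(n_seizures = 12, monitoring_days = 7,
                            n_channels = 6, n_bands = 6,
                            windows_per_seizure = c(15, 30),
                            l_true = 1, c_true = 0, n_true = 0,
                            within_noise_sd = 0.02, min_gap_days = 0.2,
                            squash = c("affine", "logistic"),
                            center_lambda = TRUE, seed = 1L) {
  squash <- match.arg(squash)
  n_edges <- n_channels * (n_channels - 1) / 2
  times <- sample_seizure_times(n_seizures, monitoring_days, min_gap_days,
                                seed = seed)
  g <- latent_drift(times, l_true, c_true, n_true, seed = seed + 1L)
  lambda <- if (squash == "affine") {
    rg <- max(g) - min(g)
    if (rg > 0) (g - min(g)) / rg else rep(0.5, length(g))
  } else {
    stats::plogis(if (center_lambda) g - stats::median(g) else g)
  }
  skel <- pathway_skeleton(max(windows_per_seizure), n_edges, n_bands,
                           seed = seed + 2L)
  win_range <- seq(windows_per_seizure[1], windows_per_seizure[2])
  n_win <- withr::with_seed(
    seed + 3L,
    win_range[sample.int(length(win_range), n_seizures, replace = TRUE)]
  )
  ids <- sprintf("sz%02d", seq_len(n_seizures))
  seizures <- lapply(seq_len(n_seizures), function(i) {
    synthesize_seizure_connectivity(
      skel, lambda[i], within_noise_sd,
      n_windows = n_win[i], seed = seed + 10L + i, seizure_id = ids[i]
    )
  })
  structure(
    list(
      seizures = seizures,
      times = times,
      annotations = tibble::tibble(
        seizure_id = ids, onset_days = times, n_windows = n_win,
        lambda = lambda, g = g
      ),
      lambda = lambda, g = g,
      params = list(
        n_seizures = n_seizures, monitoring_days = monitoring_days,
        n_channels = n_channels, n_bands = n_bands,
        windows_per_seizure = windows_per_seizure,
        l_true = l_true, c_true = c_true, n_true = n_true,
        within_noise_sd = within_noise_sd, min_gap_days = min_gap_days,
        seed = seed
      )
    ),
    class = "ictal_cohort"
  )
}

#' @export
print.ictal_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ictal_cohort> %d seizures over %.1f d (l=%g, c=%g, n=%g, seed=%d)\n",
    p$n_seizures, max(x$times), p$l_true, p$c_true, p$n_true, p$seed
  ))
  invisible(x)
}
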