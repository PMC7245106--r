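# Preprocessing and sliding-window band-averaged coherence: the feature
# space in which seizure pathways are compared.

#' Preprocessing configuration
#'
#' @param target_fs Target sampling rate in Hz after downsampling. Must
#'   exceed 300 Hz so the 150-Hz band edge stays below Nyquist.
#' @param bandpass Length-2 passband in Hz (default 1--150, fourth-order
#'   zero-phase Butterworth).
#' @param filter_order Butterworth order (default 4).
#' @param line_freq Mains frequency, 50 or 60 Hz; notch filters are applied
#'   at every harmonic up to 150 Hz.
#' @param notch_width Total stop-band width of each notch in Hz (default 2).
#' @param max_gap_s Longest run of missing samples that may be linearly
#'   interpolated, in seconds (default 0.05). Longer gaps reject the seizure;
#'   raise this per seizure only as a documented exception.
#' @param excluded_channels Character vector of channels to drop (from visual
#'   inspection) before re-referencing.
#' @return A list of class `ictal_preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 512, bandpass = c(1, 150),
                              filter_order = 4, line_freq = 50,
                              notch_width = 2, max_gap_s = 0.05,
                              excluded_channels = character()) {
  if (!(line_freq %in% c(50, 60))) rlang::abort("`line_freq` must be 50 or 60 Hz.")
  if (bandpass[1] <= 0 || bandpass[2] >= target_fs / 2) {
    rlang::abort("`bandpass` must lie strictly within (0, target_fs / 2).")
  }
  structure(
    list(
      target_fs = target_fs, bandpass = bandpass, filter_order = filter_order,
      line_freq = line_freq, notch_width = notch_width, max_gap_s = max_gap_s,
      excluded_channels = excluded_channels
    ),
    class = "ictal_preprocess_config"
  )
}

interpolate_gaps <- function(x, mask, fs, max_gap_s, seizure_id = NULL) {
  if (!any(mask)) return(x)
  r <- rle(mask)
  run_len <- r$lengths[r$values]
  if (length(run_len) && max(run_len) / fs > max_gap_s) {
    rlang::abort(sprintf(
      "Seizure %s rejected: missing-data gap of %.3f s exceeds max_gap_s = %.3f s.",
      seizure_id %||% "?", max(run_len) / fs, max_gap_s
    ))
  }
  idx <- seq_along(x)
  stats::approx(idx[!mask], x[!mask], xout = idx, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Butterworth bandpass/bandstop designed as cascaded biquads (second-order
# sections): analog lowpass prototype, band transform, bilinear transform
# with prewarping. High-order designs with narrow normalized bands are
# numerically unusable as single transfer-function polynomials (the form
# signal::butter returns), so the sections are built analytically.
butter_sos <- function(order, w, type = c("pass", "stop")) {
  type <- match.arg(type)
  if (order %% 2 != 0) rlang::abort("Even filter order required.")
  Om <- tan(pi * w / 2)               # prewarped analog band edges
  w0 <- sqrt(prod(Om))
  B <- Om[2] - Om[1]
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP prototype poles
  if (type == "pass") {
    disc <- sqrt(proto^2 * B^2 - 4 * w0^2 + 0i)
    apoles <- c((proto * B + disc) / 2, (proto * B - disc) / 2)
    zzeros <- c(rep(1, order), rep(-1, order))
    zref <- exp(1i * 2 * atan(w0))    # band center
  } else {
    u <- B / proto
    disc <- sqrt(u^2 - 4 * w0^2 + 0i)
    apoles <- c((u + disc) / 2, (u - disc) / 2)
    th <- 2 * atan(w0)
    zzeros <- rep(exp(c(1i, -1i) * th), order)
    zref <- 1 + 0i                    # DC
  }
  zpoles <- (1 + apoles) / (1 - apoles)

  pair_conj <- function(r) {
    out <- list()
    while (length(r) > 1) {
      z1 <- r[1]
      r <- r[-1]
      j <- which.min(Mod(r - Conj(z1)))
      out[[length(out) + 1]] <- c(z1, r[j])
      r <- r[-j]
    }
    out
  }
  pp <- pair_conj(zpoles)
  zp <- if (type == "pass") {
    replicate(order, c(1, -1), simplify = FALSE)
  } else {
    pair_conj(zzeros)
  }
  Hsec <- function(b, a, z) {
    (b[1] + b[2] / z + b[3] / z^2) / (a[1] + a[2] / z + a[3] / z^2)
  }
  lapply(seq_along(pp), function(i) {
    b <- Re(c(1, -(zp[[i]][1] + zp[[i]][2]), zp[[i]][1] * zp[[i]][2]))
    a <- Re(c(1, -(pp[[i]][1] + pp[[i]][2]), pp[[i]][1] * pp[[i]][2]))
    b <- b / Mod(Hsec(b, a, zref))    # unit gain per section at the reference
    list(b = b, a = a)
  })
}

# Zero-phase (forward-backward) filtering of a biquad cascade. Each pass
# starts from the section's steady-state initial conditions and the signal is
# extended by odd reflection, so neither end carries a start-up transient.
filtfilt_sos <- function(sos, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1)
  ext <- c(2 * x[1] - rev(x[2:(p + 1)]),
           x,
           2 * x[n] - rev(x[(n - p):(n - 1)]))
  m <- do.call(rbind, lapply(sos, function(s) c(s$b, s$a[2:3])))
  y <- sosfiltfilt_rcpp(m, ext)
  y[(p + 1):(p + n)]
}

#' Preprocess an ictal recording
#'
#' Applies the standard ictal iEEG cleaning chain: drop excluded channels,
#' linearly interpolate short missing-data gaps, downsample to `target_fs`
#' (polyphase, anti-aliased), re-reference to the common average, bandpass
#' filter 1--150 Hz (zero-phase Butterworth), and notch filter the mains
#' frequency and its harmonics up to 150 Hz.
#'
#' @param rec An `ictal_recording`.
#' @param config An `ictal_preprocess_config`.
#' @return A preprocessed `ictal_recording` at `target_fs`; the channel mean
#'   across channels is zero at every sample.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "ictal_recording"))
  keep <- !(rec$channel_labels %in% config$excluded_channels)
  if (sum(keep) < 2) rlang::abort("Fewer than 2 channels remain after exclusions.")
  x <- rec$samples[keep, , drop = FALSE]
  mask <- if (!is.null(rec$missing_mask)) rec$missing_mask[keep, , drop = FALSE] else NULL
  if (rec$fs < 2 * config$bandpass[2]) {
    rlang::abort(sprintf(
      "Sampling rate %g Hz cannot support the %g-Hz band edge (need fs >= %g Hz).",
      rec$fs, config$bandpass[2], 2 * config$bandpass[2]
    ))
  }

  if (!is.null(mask)) {
    for (ch in seq_len(nrow(x))) {
      x[ch, ] <- interpolate_gaps(x[ch, ], mask[ch, ], rec$fs, config$max_gap_s,
                                  rec$seizure_id)
    }
  }

  fs <- rec$fs
  if (fs != config$target_fs) {
    # signal::resample performs polyphase rational resampling with an
    # anti-aliasing FIR; use a rational approximation of the rate ratio.
    frac <- MASS::fractions(config$target_fs / fs, cycles = 8)
    pq <- as.numeric(strsplit(attr(frac, "fracs"), "/")[[1]])
    if (length(pq) == 1) pq <- c(pq, 1)
    x <- t(apply(x, 1, function(ch) signal::resample(ch, pq[1], pq[2])))
    fs <- config$target_fs
  }

  # common average reference
  x <- sweep(x, 2, colMeans(x))

  bp <- butter_sos(config$filter_order, config$bandpass / (fs / 2), "pass")
  harmonics <- config$line_freq * seq_len(floor(config$bandpass[2] / config$line_freq))
  notches <- lapply(harmonics, function(h) {
    stop_band <- c(h - config$notch_width / 2, h + config$notch_width / 2) / (fs / 2)
    butter_sos(config$filter_order, stop_band, "stop")
  })
  pad <- round(2 * fs)
  x <- t(apply(x, 1, function(ch) {
    ch <- filtfilt_sos(bp, ch, pad)
    for (notch in notches) ch <- filtfilt_sos(notch, ch, pad)
    ch
  }))

  recording(x, fs, rec$channel_labels[keep], rec$seizure_id, rec$onset_datetime)
}

# Welch cross-spectral matrix summed over frequency band bins.
# Returns, for each band, S[i,j] = sum_{f in band} P_ij(f) where P_ij is the
# Welch-averaged cross-spectrum (Hann taper). Constant scale factors cancel
# in the coherence ratio and are omitted.
welch_band_cross <- function(x, fs, bands, welch_win = 2, welch_overlap = 1) {
  n_ch <- nrow(x)
  seg_len <- round(welch_win * fs)
  step <- round((welch_win - welch_overlap) * fs)
  n <- ncol(x)
  if (n < seg_len) rlang::abort("Window shorter than one Welch segment.")
  starts <- seq(1, n - seg_len + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)) # Hann
  freqs <- (seq_len(seg_len) - 1) * fs / seg_len
  band_bins <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands$f1[b] & freqs < bands$f2[b]) # half-open [f1, f2)
  })
  S <- lapply(band_bins, function(bb) matrix(0 + 0i, n_ch, n_ch))
  for (s0 in starts) {
    seg <- x[, s0:(s0 + seg_len - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- stats::mvfft(t(seg * rep(taper, each = n_ch)))  # seg_len x n_ch
    for (b in seq_along(band_bins)) {
      Xb <- X[band_bins[[b]], , drop = FALSE]
      S[[b]] <- S[[b]] + t(Conj(Xb)) %*% Xb   # S[i,j] += sum_f X_i X_j*
    }
  }
  S
}

#' Band-averaged coherence of one time window
#'
#' For each frequency band, computes
#' `C_ij = |sum_f P_ij(f)|^2 / (sum_f P_ii(f) * sum_f P_jj(f))`,
#' with cross- and autospectra estimated by Welch's method (2-s segments,
#' 1-s overlap, Hann taper) and band sums taken over the half-open interval
#' `[f1, f2)` on the discrete frequency grid.
#'
#' @param x Numeric matrix, channels by samples: one analysis window
#'   (nominally 10 s).
#' @param fs Sampling rate in Hz.
#' @param bands Band table as from [band_set()].
#' @param welch_win,welch_overlap Welch segment length and overlap in
#'   seconds (defaults 2 and 1).
#' @return A 3-D array `n x n x n_bands` of coherences in \[0, 1\];
#'   each slice is symmetric with unit diagonal.
#' @export
band_coherence_window <- function(x, fs, bands = band_set(),
                                  welch_win = 2, welch_overlap = 1) {
  x <- as.matrix(x)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    rlang::abort(sprintf(
      "Channel %d has zero variance: autospectrum degenerate.", which(v == 0)[1]
    ))
  }
  S <- welch_band_cross(x, fs, bands, welch_win, welch_overlap)
  out <- array(NA_real_, c(nrow(x), nrow(x), nrow(bands)),
               dimnames = list(NULL, NULL, bands$band))
  for (b in seq_along(S)) {
    auto <- Re(diag(S[[b]]))
    C <- Mod(S[[b]])^2 / outer(auto, auto)
    C <- pmin(pmax((C + t(C)) / 2, 0), 1)  # symmetrize; clip fp overshoot
    diag(C) <- 1
    out[, , b] <- C
  }
  out
}

#' Vectorize and L1-normalize a window's coherence matrices
#'
#' Rearranges the upper-triangular, off-diagonal elements of each band's
#' coherence matrix into a vector (row-major edge order), normalizes each
#' band's vector to sum 1, and concatenates the bands delta through
#' high-gamma.
#'
#' @param mats A `n x n x n_bands` array as from [band_coherence_window()].
#' @return Numeric vector of length `n_bands * (n^2 - n) / 2`, with a
#'   `band_index` attribute.
#' @export
vectorize_normalize <- function(mats) {
  stopifnot(length(dim(mats)) == 3)
  n <- dim(mats)[1]
  n_bands <- dim(mats)[3]
  # row-major upper triangle: transpose, then take the lower triangle
  sel <- lower.tri(matrix(0, n, n))
  vecs <- lapply(seq_len(n_bands), function(b) {
    m <- mats[, , b]
    if (any(m < 0)) rlang::abort("Coherence matrices must be nonnegative.")
    v <- t(m)[sel]
    s <- sum(v)
    if (s <= 0) rlang::abort(sprintf("Band %d is all zero: L1 normalization undefined.", b))
    v / s
  })
  out <- unlist(vecs)
  attr(out, "band_index") <- band_block_index(n * (n - 1) / 2, n_bands)
  out
}

#' Sliding-window connectivity of one seizure
#'
#' Applies a 10-s sliding window with 1-s steps (9-s overlap) to a
#' preprocessed recording, computes band-averaged coherence per window, and
#' assembles the per-band L1-normalized feature vectors into a connectivity
#' time series. A seizure of duration `d` seconds yields
#' `floor(d - 10) + 1` windows.
#'
#' @param rec Preprocessed `ictal_recording`.
#' @param bands Band table as from [band_set()].
#' @param window_s,step_s Analysis window length and stride in seconds
#'   (defaults 10 and 1).
#' @param welch_win,welch_overlap Welch parameters (defaults 2 and 1 s).
#' @return An `ictal_cts` with window start times in seconds.
#' @export
seizure_connectivity <- function(rec, bands = band_set(), window_s = 10,
                                 step_s = 1, welch_win = 2, welch_overlap = 1) {
  stopifnot(inherits(rec, "ictal_recording"))
  fs <- rec$fs
  n <- ncol(rec$samples)
  win_len <- round(window_s * fs)
  if (n < win_len) {
    rlang::abort(sprintf(
      "Seizure %s rejected: duration %.2f s is shorter than the %g-s analysis window.",
      rec$seizure_id %||% "?", n / fs, window_s
    ))
  }
  starts <- seq(1, n - win_len + 1, by = round(step_s * fs))
  cols <- lapply(starts, function(s0) {
    mats <- band_coherence_window(rec$samples[, s0:(s0 + win_len - 1), drop = FALSE],
                                  fs, bands, welch_win, welch_overlap)
    vectorize_normalize(mats)
  })
  feats <- do.call(cbind, cols)
  connectivity_ts(feats, attr(cols[[1]], "band_index"),
                  window_times = (starts - 1) / fs,
                  seizure_id = rec$seizure_id)
}

#' Assemble the cohort connectivity matrix V
#'
#' Horizontally concatenates the per-seizure connectivity time series into
#' one features-by-windows matrix `V`, keeping per-window seizure labels.
#'
#' @param cts_list List of `ictal_cts` from one patient (same feature space).
#' @return A list with `V` (matrix), `band_index`, and `windows` (tibble with
#'   `seizure_id`, `window`, `time_s`).
#' @export
assemble_cohort_matrix <- function(cts_list) {
  stopifnot(length(cts_list) >= 1)
  dims <- vapply(cts_list, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    rlang::abort("All seizures must share one feature space (equal feature counts).")
  }
  V <- do.call(cbind, lapply(cts_list, unclass))
  windows <- dplyr::bind_rows(lapply(seq_along(cts_list), function(i) {
    x <- cts_list[[i]]
    tibble::tibble(
      seizure_id = attr(x, "seizure_id") %||% sprintf("sz%02d", i),
      window = seq_len(ncol(x)),
      time_s = attr(x, "window_times")
    )
  }))
  list(V = V, band_index = band_index_of(cts_list[[1]]), windows = windows)
}
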