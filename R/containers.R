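# Core containers shared by every stage of the pipeline.
#
# Connectivity feature vectors live in a nonnegative space where each of the
# six frequency-band blocks is L1-normalized to sum 1, so a feature matrix is
# always accompanied by a band_block_index mapping features to bands.

#' Canonical frequency band set
#'
#' The six frequency bands used throughout the package: delta 1--4, theta
#' 4--8, alpha 8--13, beta 13--30, gamma 30--80 and high-gamma 80--150 Hz.
#' Band intervals are treated as half-open `[f1, f2)` when summing spectra so
#' that touching edges (4, 8, 13, 30, 80 Hz) are never double-counted.
#'
#' @return A tibble with columns `band`, `f1`, `f2` (Hz), ordered from delta
#'   to high-gamma.
#' @export
#' @examples
#' band_set()
band_set <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"),
    f1 = c(1, 4, 8, 13, 30, 80),
    f2 = c(4, 8, 13, 30, 80, 150)
  )
}

#' Band block index for a connectivity feature vector
#'
#' @param n_edges Number of channel-pair edges per band, `(n^2 - n) / 2`.
#' @param n_bands Number of frequency bands (default 6).
#' @return Integer vector of length `n_edges * n_bands` mapping each feature
#'   to its band (1 = delta, ..., 6 = high-gamma).
#' @export
band_block_index <- function(n_edges, n_bands = 6L) {
  rep(seq_len(n_bands), each = n_edges)
}

#' Edge index for the upper-triangle vectorization
#'
#' Features within a band block are ordered row-major over the upper triangle
#' of the channel-by-channel matrix: (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param n_channels Number of channels.
#' @return Tibble with columns `edge`, `i`, `j` (i < j).
#' @export
edge_index <- function(n_channels) {
  ij <- which(upper.tri(matrix(0, n_channels, n_channels)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tibble::tibble(edge = seq_len(nrow(ij)), i = ij[, 1], j = ij[, 2])
}

#' Construct a connectivity time series
#'
#' A connectivity time series holds one seizure's sliding-window network
#' features: a nonnegative `features x windows` matrix in which every
#' frequency-band block of every window (column) sums to 1.
#'
#' @param features Nonnegative numeric matrix, features by windows.
#' @param band_index Integer vector mapping rows of `features` to bands.
#' @param window_times Numeric vector of window start times in seconds
#'   (left-aligned); defaults to `0, 1, 2, ...`.
#' @param seizure_id Optional identifier.
#' @param validate Check the band-block normalization invariant (default TRUE).
#' @return An object of class `ictal_cts`.
#' @export
connectivity_ts <- function(features, band_index, window_times = NULL,
                            seizure_id = NULL, validate = TRUE) {
  features <- as.matrix(features)
  dimnames(features) <- NULL
  band_index <- as.integer(band_index)
  if (length(band_index) != nrow(features)) {
    rlang::abort("`band_index` must have one entry per feature row.")
  }
  if (is.null(window_times)) window_times <- seq_len(ncol(features)) - 1
  if (length(window_times) != ncol(features)) {
    rlang::abort("`window_times` must have one entry per window column.")
  }
  x <- structure(features,
    band_index = band_index,
    window_times = as.numeric(window_times),
    seizure_id = seizure_id,
    class = c("ictal_cts", "matrix", "array")
  )
  if (validate) validate_cts(x)
  x
}

#' @export
print.ictal_cts <- function(x, ...) {
  cat(sprintf(
    "<ictal_cts> %d features x %d windows (%d bands)%s\n",
    nrow(x), ncol(x), length(unique(attr(x, "band_index"))),
    if (!is.null(attr(x, "seizure_id"))) paste0(" seizure ", attr(x, "seizure_id")) else ""
  ))
  invisible(x)
}

validate_cts <- function(x, tol = 1e-9) {
  if (any(x < 0)) rlang::abort("Connectivity features must be nonnegative.")
  bi <- attr(x, "band_index")
  sums <- rowsum(unclass(x), bi)
  if (any(abs(sums - 1) > tol)) {
    rlang::abort(sprintf(
      "Band-block L1 normalization violated (max deviation %.3g).",
      max(abs(sums - 1))
    ))
  }
  invisible(x)
}

band_index_of <- function(x) attr(x, "band_index")
window_times_of <- function(x) attr(x, "window_times")

# Renormalize each band block of each column to sum 1. Errors if a block is
# entirely zero (normalization undefined).
renormalize_blocks <- function(features, band_index) {
  sums <- rowsum(features, band_index)          # n_bands x m
  if (any(sums <= 0)) {
    bad <- which(sums <= 0, arr.ind = TRUE)
    rlang::abort(sprintf(
      "All-zero band block: band %d of window %d cannot be L1-normalized.",
      bad[1, 1], bad[1, 2]
    ))
  }
  features / sums[band_index, , drop = FALSE]
}

#' Construct a recording
#'
#' Container for one seizure's multichannel iEEG clip.
#'
#' @param samples Numeric matrix, channels by time samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names.
#' @param seizure_id Optional identifier.
#' @param onset_datetime Optional `POSIXct` seizure onset.
#' @param missing_mask Optional logical matrix (same shape as `samples`);
#'   TRUE marks missing samples to be interpolated during preprocessing.
#' @return An object of class `ictal_recording`.
#' @export
recording <- function(samples, fs, channel_labels = NULL, seizure_id = NULL,
                      onset_datetime = NULL, missing_mask = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) rlang::abort("A recording needs at least 2 channels.")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    rlang::abort("`channel_labels` must match the number of channels.")
  }
  if (!is.null(missing_mask)) {
    missing_mask <- as.matrix(missing_mask)
    stopifnot(all(dim(missing_mask) == dim(samples)))
  }
  structure(
    list(
      samples = samples, fs = as.numeric(fs),
      channel_labels = channel_labels, seizure_id = seizure_id,
      onset_datetime = onset_datetime, missing_mask = missing_mask
    ),
    class = "ictal_recording"
  )
}

#' @export
print.ictal_recording <- function(x, ...) {
  cat(sprintf(
    "<ictal_recording> %d channels x %.1f s @ %g Hz%s\n",
    nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
    if (!is.null(x$seizure_id)) paste0(" [", x$seizure_id, "]") else ""
  ))
  invisible(x)
}

#' Tidy a connectivity time series
#'
#' @param x An `ictal_cts`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, window) cell: `feature`,
#'   `band`, `window`, `time_s`, `value`.
#' @export
tidy.ictal_cts <- function(x, ...) {
  bi <- attr(x, "band_index")
  wt <- attr(x, "window_times")
  tibble::tibble(
    feature = rep(seq_len(nrow(x)), times = ncol(x)),
    band = rep(bi, times = ncol(x)),
    window = rep(seq_len(ncol(x)), each = nrow(x)),
    time_s = rep(wt, each = nrow(x)),
    value = as.vector(unclass(x))
  )
}
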