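# Plain-text persistence for every container, a minimal EDF reader/writer
# for raw multichannel clips, and a loader for deposited NMF factorizations.

#' Write / read a square seizure-pair matrix as CSV
#'
#' Seizure ids are kept as the first column and the header row.
#'
#' @param m Matrix (dissimilarity or temporal distance) with id dimnames.
#' @param path Output CSV path.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` returns the matrix with class `ictal_dissim`.
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- data.frame(seizure_id = ids, unclass(m), check.names = FALSE)
  colnames(df) <- c("seizure_id", ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (colnames(df)[1] != "seizure_id") {
    rlang::abort("Malformed matrix CSV: first column must be `seizure_id`.")
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(colnames(m) == ids)) {
    rlang::abort("Malformed matrix CSV: header ids do not match the id column.")
  }
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("ictal_dissim", "matrix", "array"))
}

#' Write / read a temporal correlation pattern as CSV
#' @param tcp An `ictal_tcp` tibble.
#' @param path CSV path.
#' @export
write_tcp_csv <- function(tcp, path) {
  utils::write.csv(as.data.frame(unclass(tcp)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tcp_csv
#' @export
read_tcp_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("timescale", "n_pairs", "new_pairs", "valid", "rho")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    rlang::abort(paste0("Malformed TCP CSV: missing column(s) ",
                        paste(miss, collapse = ", "), "."))
  }
  out <- tibble::as_tibble(df[need])
  class(out) <- c("ictal_tcp", class(out))
  out
}

#' Write / read a connectivity time series as a plain-text bundle
#'
#' The bundle is a directory of CSV/JSON files: `features.csv` (features by
#' windows), `band_index.csv`, `window_times.csv` and `meta.json`, so the
#' container survives any text-only transport.
#'
#' @param cts An `ictal_cts`.
#' @param path Directory to create.
#' @export
write_cts_bundle <- function(cts, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(unclass(cts)), file.path(path, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(band = band_index_of(cts)),
                   file.path(path, "band_index.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = window_times_of(cts)),
                   file.path(path, "window_times.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seizure_id = attr(cts, "seizure_id")),
    file.path(path, "meta.json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_cts_bundle
#' @export
read_cts_bundle <- function(path) {
  feats <- as.matrix(utils::read.csv(file.path(path, "features.csv")))
  bi <- utils::read.csv(file.path(path, "band_index.csv"))$band
  wt <- utils::read.csv(file.path(path, "window_times.csv"))$time_s
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  dimnames(feats) <- NULL
  connectivity_ts(feats, bi, wt, seizure_id = meta$seizure_id)
}

#' Read and validate a seizure annotation table
#'
#' Expected columns: `seizure_id`, `onset_days` (fractional days since the
#' first seizure) or `onset_datetime` (ISO 8601); optional
#' `excluded_channels` (semicolon-separated) and `line_freq`. Malformed rows
#' are reported by row number and column name.
#'
#' @param path CSV path.
#' @return Tibble with `seizure_id`, `onset_days` and any optional columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"seizure_id" %in% colnames(df)) {
    rlang::abort("Annotation table lacks column `seizure_id`.")
  }
  if ("onset_days" %in% colnames(df)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$onset_days))))
    if (length(bad)) {
      rlang::abort(sprintf("Annotation row %d: column `onset_days` is not numeric.", bad[1]))
    }
    df$onset_days <- as.numeric(df$onset_days)
  } else if ("onset_datetime" %in% colnames(df)) {
    ts <- as.POSIXct(df$onset_datetime, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    bad <- which(is.na(ts))
    if (length(bad)) {
      rlang::abort(sprintf("Annotation row %d: column `onset_datetime` is not a valid timestamp.",
                           bad[1]))
    }
    df$onset_days <- as.numeric(difftime(ts, min(ts), units = "days"))
  } else {
    rlang::abort("Annotation table needs `onset_days` or `onset_datetime`.")
  }
  if (is.unsorted(df$onset_days)) {
    rlang::abort("Annotation rows must be sorted by onset time.")
  }
  tibble::as_tibble(df)
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one data record per
#' second, physical range set from the data. Sufficient for storing and
#' re-reading synthetic or preprocessed clips; not a full EDF+ implementation
#' (no annotations channel).
#'
#' @param rec An `ictal_recording`; `fs` must be a positive integer.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ictal_recording"))
  fs <- rec$fs
  if (fs != round(fs)) rlang::abort("EDF writer requires an integer sampling rate.")
  x <- rec$samples
  ns <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) rlang::abort("Recording shorter than one 1-s data record.")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  phys_min <- apply(x, 1, min)
  phys_max <- apply(x, 1, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  dig_min <- -32768
  dig_max <- 32767
  digital <- round(sweep(sweep(x, 1, phys_min), 1, span, "/") * (dig_max - dig_min) + dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Synthetic recording", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 + ns * 256, 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8),
    pad_ascii(1, 8),
    pad_ascii(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_ascii, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(sprintf("%.6g", phys_min), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)                       # reserved
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(digital[, cols])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [write_edf()]; reads a standard 16-bit EDF into an
#' [recording()].
#'
#' @param path `.edf` path.
#' @return An `ictal_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1) rlang::abort("Channels with mixed sampling rates are not supported.")
  fs <- spr[1] / rec_dur
  x <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2, endian = "little")
    x[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- matrix(block, ns, byrow = TRUE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  x <- sweep(sweep(x, 1, dig_min), 1, gain, "*") + phys_min
  recording(x, fs, channel_labels = labels)
}

#' Read a deposited NMF factorization
#'
#' Loads a patient's deposited factorization (basis matrix `W`, coefficient
#' matrix `H`, and per-window seizure labels) exported as plain CSV:
#' `W.csv` (features x rank), `H.csv` (rank x windows),
#' `windows.csv` (column `seizure_id`, one row per window) and
#' `band_index.csv` (column `band`). This is the layout used to reproduce
#' published per-patient dissimilarities from archived factorizations.
#'
#' @param path Directory containing the four CSV files.
#' @return List with `W`, `H`, `band_index`, `seizure_id` (per window).
#' @export
read_nmf_deposit <- function(path) {
  need <- file.path(path, c("W.csv", "H.csv", "windows.csv", "band_index.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    rlang::abort(paste0("Deposit files not found: ",
                        paste(basename(missing), collapse = ", "),
                        " under ", path))
  }
  W <- as.matrix(utils::read.csv(need[1]))
  H <- as.matrix(utils::read.csv(need[2]))
  windows <- utils::read.csv(need[3])
  bi <- utils::read.csv(need[4])$band
  dimnames(W) <- dimnames(H) <- NULL
  if (ncol(W) != nrow(H)) rlang::abort("Deposit W and H ranks do not match.")
  if (nrow(W) != length(bi)) rlang::abort("Deposit band index does not match W.")
  if (ncol(H) != nrow(windows)) rlang::abort("Deposit window labels do not match H.")
  list(W = W, H = H, band_index = bi, seizure_id = as.character(windows$seizure_id))
}

#' Seizure dissimilarities from a deposited factorization
#'
#' Reconstructs `V* = W x H`, renormalizes each band block, splits windows
#' by seizure, and computes the DTW dissimilarity matrix — the path used to
#' recompute published per-patient dissimilarity values from archived NMF
#' factorizations.
#'
#' @param deposit A list as returned by [read_nmf_deposit()].
#' @return An `ictal_dissim` matrix with the deposit's seizure ids.
#' @export
dissimilarity_from_deposit <- function(deposit) {
  model <- structure(list(W = deposit$W, H = deposit$H, r = ncol(deposit$W)),
                     class = "ictal_nmf")
  V_star <- denoise_reconstruct(model, deposit$band_index)
  ids <- unique(deposit$seizure_id)
  seizures <- lapply(ids, function(id) {
    connectivity_ts(V_star[, deposit$seizure_id == id, drop = FALSE],
                    deposit$band_index, seizure_id = id)
  })
  dissimilarity_matrix(seizures, ids = ids)
}
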