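# Pairwise seizure dissimilarity by L1 dynamic time warping.
#
# Two seizures are compared as pathways through connectivity space: their
# window sequences are aligned by DTW (steps (1,0), (0,1), (1,1), unit
# weights, fixed endpoints, no global band constraint) minimizing the total
# L1 distance, and the dissimilarity is the mean per-step distance over the
# warped path. The measure is speed-invariant but not a metric (the triangle
# inequality need not hold).

as_feature_matrix <- function(x) {
  if (inherits(x, "ictal_cts")) {
    m <- unclass(x)
    attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
    m
  } else {
    as.matrix(x)
  }
}

#' Dynamic time warping of two connectivity time courses under L1 cost
#'
#' @param A,B Connectivity time series (`ictal_cts`) or plain
#'   features-by-windows matrices with the same feature dimension.
#' @return An object of class `ictal_warp`: `path` (tibble with window
#'   indices `a`, `b` and per-step L1 distance `d`), `total_cost`, `K`
#'   (path length).
#' @export
dtw_l1 <- function(A, B) {
  A <- as_feature_matrix(A)
  B <- as_feature_matrix(B)
  if (nrow(A) != nrow(B)) {
    rlang::abort("Feature dimensions differ: seizures are not comparable.")
  }
  m_a <- ncol(A)
  m_b <- ncol(B)
  cost <- matrix(0, m_a, m_b)
  for (a in seq_len(m_a)) cost[a, ] <- colSums(abs(B - A[, a]))

  D <- matrix(Inf, m_a + 1, m_b + 1)
  D[1, 1] <- 0
  for (a in seq_len(m_a)) {
    for (b in seq_len(m_b)) {
      D[a + 1, b + 1] <- cost[a, b] +
        min(D[a, b], D[a, b + 1], D[a + 1, b])
    }
  }

  # backtrack, preferring the diagonal step on ties
  a <- m_a; b <- m_b
  path_a <- integer(0); path_b <- integer(0)
  while (a >= 1 && b >= 1) {
    path_a <- c(a, path_a); path_b <- c(b, path_b)
    if (a == 1 && b == 1) break
    preds <- c(D[a, b], D[a, b + 1], D[a + 1, b])  # diag, up, left
    step <- which.min(preds)
    if (step == 1) { a <- a - 1; b <- b - 1 }
    else if (step == 2) a <- a - 1
    else b <- b - 1
  }
  d <- cost[cbind(path_a, path_b)]
  structure(
    list(path = tibble::tibble(a = path_a, b = path_b, d = d),
         total_cost = D[m_a + 1, m_b + 1], K = length(d)),
    class = "ictal_warp"
  )
}

#' @export
print.ictal_warp <- function(x, ...) {
  cat(sprintf("<ictal_warp> %d steps, total L1 cost %.4g\n", x$K, x$total_cost))
  invisible(x)
}

#' Dissimilarity between two seizure pathways
#'
#' The mean L1 distance across all warped time points of the DTW alignment.
#' Zero iff the two pathways are identical up to time warping; bounded above
#' by 12 for per-band L1-normalized features (2 per band over 6 bands).
#'
#' @inheritParams dtw_l1
#' @return Nonnegative scalar, symmetric in `A`, `B`.
#' @export
seizure_dissimilarity <- function(A, B) {
  w <- dtw_l1(A, B)
  w$total_cost / w$K
}

#' Seizure dissimilarity matrix of one patient
#'
#' @param seizures List of connectivity time series from one patient (same
#'   feature space).
#' @param ids Optional seizure identifiers (default: `seizure_id` attributes
#'   or `sz01`, `sz02`, ...).
#' @return A symmetric, zero-diagonal matrix of class `ictal_dissim` with
#'   seizure ids as dimnames.
#' @export
dissimilarity_matrix <- function(seizures, ids = NULL) {
  S <- length(seizures)
  if (S < 2) rlang::abort("Need at least 2 seizures.")
  dims <- vapply(seizures, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    rlang::abort("Mixed feature dimensions: all seizures must share one feature space.")
  }
  if (is.null(ids)) {
    ids <- vapply(seq_len(S), function(i) {
      attr(seizures[[i]], "seizure_id") %||% sprintf("sz%02d", i)
    }, character(1))
  }
  D <- matrix(0, S, S, dimnames = list(ids, ids))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      D[i, j] <- D[j, i] <- seizure_dissimilarity(seizures[[i]], seizures[[j]])
    }
  }
  structure(D, class = c("ictal_dissim", "matrix", "array"))
}

#' Tidy a dissimilarity (or temporal distance) matrix
#'
#' @param x An `ictal_dissim` or plain symmetric matrix.
#' @param ... Unused.
#' @return Tibble of upper-triangle pairs: `seizure_a`, `seizure_b`, `value`.
#' @export
tidy.ictal_dissim <- function(x, ...) {
  m <- unclass(x)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    seizure_a = ids[ut[, 1]], seizure_b = ids[ut[, 2]],
    value = m[ut]
  )
}

#' Per-band contributions to a seizure dissimilarity
#'
#' Decomposes the dissimilarity between two seizures into the six frequency
#' bands: the warp path is computed once on the full feature vectors, then
#' the mean warped L1 distance is evaluated per band block. The six
#' contributions sum to the total dissimilarity.
#'
#' @param A,B Connectivity time series (`ictal_cts`) sharing a feature space.
#' @param band_index Optional band index (default: taken from `A`).
#' @return Tibble with columns `band` (index), `contribution`.
#' @export
band_contributions <- function(A, B, band_index = NULL) {
  if (is.null(band_index)) band_index <- band_index_of(A)
  if (is.null(band_index)) rlang::abort("No band index available.")
  w <- dtw_l1(A, B)
  Am <- as_feature_matrix(A)
  Bm <- as_feature_matrix(B)
  diffs <- abs(Am[, w$path$a, drop = FALSE] - Bm[, w$path$b, drop = FALSE])
  per_band <- rowsum(diffs, band_index)    # n_bands x K
  tibble::tibble(
    band = sort(unique(band_index)),
    contribution = rowMeans(per_band)
  )
}

#' Project connectivity windows to 2D by Sammon mapping
#'
#' Embeds window feature vectors in two dimensions by Sammon's nonlinear
#' mapping on their pairwise L1 (cityblock) distances, initialized from
#' classical (Torgerson) MDS. Duplicate windows (zero distances) are
#' collapsed before the mapping and restored afterwards, so they cannot blow
#' up the Sammon criterion.
#'
#' @param X Features-by-windows matrix (or `ictal_cts`), or a `dist` object.
#' @param seed Integer seed (jitters degenerate initial configurations).
#' @param niter Maximum Sammon iterations (default 100).
#' @return Tibble with `window`, `dim1`, `dim2`; the achieved Sammon stress
#'   is in attribute `stress`.
#' @export
mds_project <- function(X, seed = 0L, niter = 100L) {
  if (inherits(X, "dist")) {
    d <- X
    n <- attr(d, "Size")
  } else {
    X <- as_feature_matrix(X)
    n <- ncol(X)
    d <- stats::dist(t(X), method = "manhattan")
  }
  if (n < 3) rlang::abort("Need at least 3 windows to project.")
  dm <- as.matrix(d)

  # collapse duplicates (zero-distance points)
  group <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- which(vapply(reps, function(r) dm[i, r] == 0, logical(1)))
    if (length(hit)) {
      group[i] <- hit[1]
    } else {
      reps <- c(reps, i)
      group[i] <- length(reps)
    }
  }
  u <- length(reps)
  if (u == 1) {
    out <- tibble::tibble(window = seq_len(n), dim1 = 0, dim2 = 0)
    attr(out, "stress") <- 0
    return(out)
  }
  du <- dm[reps, reps, drop = FALSE]
  coords_u <- if (u == 2) {
    matrix(c(-du[1, 2] / 2, du[1, 2] / 2, 0, 0), 2, 2)
  } else {
    init <- stats::cmdscale(stats::as.dist(du), k = 2)
    if (ncol(init) < 2) init <- cbind(init, 0)
    if (any(duplicated(init))) {
      init <- init + withr::with_seed(seed, matrix(stats::rnorm(u * 2, sd = 1e-6), u, 2))
    }
    fit <- MASS::sammon(stats::as.dist(du), y = init, niter = niter,
                        tol = 1e-12, trace = FALSE)
    attr(init, "stress") <- NULL
    structure(fit$points, stress = fit$stress)
  }
  out <- tibble::tibble(
    window = seq_len(n),
    dim1 = coords_u[group, 1],
    dim2 = coords_u[group, 2]
  )
  attr(out, "stress") <- attr(coords_u, "stress") %||% 0
  out
}

#' Spectrum or clusters: gap-statistic clustering of seizure pathways
#'
#' Embeds the seizure dissimilarity matrix by classical (Torgerson) MDS and
#' selects the number of k-means clusters by the gap statistic with the
#' standard one-standard-error rule (`k = 1` allowed). `k = 1` is reported as
#' a spectrum of pathways rather than distinct groupings.
#'
#' @param D Seizure dissimilarity matrix (`ictal_dissim` or symmetric
#'   matrix), at least 3 seizures.
#' @param max_k Largest cluster count examined (default `min(S - 1, 6)`).
#' @param n_ref Number of gap-statistic reference sets (default 100).
#' @param seed Integer seed.
#' @return List of class `ictal_clustering`: `k`, `assignments` (named
#'   integer vector), `gap` (tibble with `k`, `gap`, `se`), `spectrum`
#'   (TRUE iff `k == 1`).
#' @export
cluster_pathways <- function(D, max_k = NULL, n_ref = 100L, seed = 0L) {
  Dm <- unclass(as.matrix(D))
  S <- nrow(Dm)
  if (S < 3) rlang::abort("Need at least 3 seizures to assess clustering.")
  if (is.null(max_k)) max_k <- min(S - 1, 6)
  coords <- stats::cmdscale(stats::as.dist(Dm), k = min(S - 1, 5))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  km <- function(x, k) {
    if (k == 1) list(cluster = rep(1L, nrow(x)))
    else stats::kmeans(x, centers = k, nstart = 20, iter.max = 50)
  }
  gap <- withr::with_seed(seed, cluster::clusGap(coords, FUNcluster = km,
                                                 K.max = max_k, B = n_ref,
                                                 verbose = FALSE))
  tab <- gap$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  assignments <- withr::with_seed(seed + 1L, km(coords, k)$cluster)
  names(assignments) <- rownames(Dm) %||% as.character(seq_len(S))
  structure(
    list(k = k, assignments = assignments,
         gap = tibble::tibble(k = seq_len(max_k), gap = tab[, "gap"],
                              se = tab[, "SE.sim"]),
         spectrum = k == 1),
    class = "ictal_clustering"
  )
}

#' @export
print.ictal_clustering <- function(x, ...) {
  cat(sprintf("<ictal_clustering> k = %d%s\n", x$k,
              if (x$spectrum) " (spectrum of pathways)" else ""))
  invisible(x)
}
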