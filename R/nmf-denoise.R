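# Low-rank nonnegative denoising of the cohort connectivity matrix.
#
# V (features x windows) is approximately factorized as W x H with W, H >= 0
# by alternating nonnegative least squares, each subproblem solved exactly by
# block principal pivoting. The reconstruction W x H is then renormalized per
# band block so that reconstruction accuracy cannot leak into distances.

# Solve min_X ||A X - B||_F with X >= 0, given AtA = t(A) %*% A and
# AtB = t(A) %*% B (block principal pivoting; Kim & Park 2011). Columns are
# solved jointly, grouped by their passive-set pattern.
nnls_bpp <- function(AtA, AtB, max_outer = 200L) {
  r <- nrow(AtA)
  m <- ncol(AtB)
  X <- matrix(0, r, m)
  Y <- -AtB
  Fset <- matrix(FALSE, r, m)
  alpha <- rep(3L, m)
  beta <- rep(r + 1L, m)
  tol <- 1e-12
  for (outer in seq_len(max_outer)) {
    Vmat <- (Fset & (X < -tol)) | (!Fset & (Y < -tol))
    nV <- colSums(Vmat)
    if (all(nV == 0)) break
    for (j in which(nV > 0)) {
      if (nV[j] < beta[j]) {
        beta[j] <- nV[j]; alpha[j] <- 3L
        flip <- Vmat[, j]
      } else if (alpha[j] >= 1L) {
        alpha[j] <- alpha[j] - 1L
        flip <- Vmat[, j]
      } else {
        flip <- rep(FALSE, r)
        flip[max(which(Vmat[, j]))] <- TRUE
      }
      Fset[flip, j] <- !Fset[flip, j]
    }
    keys <- apply(Fset, 2, function(f) paste(as.integer(f), collapse = ""))
    for (k in unique(keys)) {
      cols <- which(keys == k)
      f <- Fset[, cols[1]]
      X[, cols] <- 0
      if (any(f)) {
        sol <- tryCatch(
          solve(AtA[f, f, drop = FALSE], AtB[f, cols, drop = FALSE]),
          error = function(e) {
            MASS::ginv(AtA[f, f, drop = FALSE]) %*% AtB[f, cols, drop = FALSE]
          }
        )
        X[f, cols] <- sol
      }
      Y[, cols] <- AtA[, f, drop = FALSE] %*% X[f, cols, drop = FALSE] - AtB[, cols]
      Y[f, cols] <- 0
    }
  }
  pmax(X, 0)
}

#' Fit a nonnegative matrix factorization
#'
#' Factorizes a nonnegative matrix `V` as `W x H` (both nonnegative) at a
#' given rank by alternating nonnegative least squares with block principal
#' pivoting; each alternating subproblem is solved exactly, so the residual
#' is monotone non-increasing over iterations.
#'
#' @param V Nonnegative numeric matrix, features by windows.
#' @param r Rank (number of basis vectors), `1 <= r < min(dim(V))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum alternating iterations (default 500).
#' @param tol Relative-change convergence tolerance on the residual
#'   (default 1e-6).
#' @return An object of class `ictal_nmf`: `W`, `H`, `r`, `seed`,
#'   `fit_error` (relative Frobenius residual), `residuals` (per iteration),
#'   `converged`, `n_iter`.
#' @export
nmf_factorize <- function(V, r, seed = 1L, max_iter = 500L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) rlang::abort("V must be nonnegative.")
  if (r < 1 || r >= min(dim(V))) {
    rlang::abort("Rank must satisfy 1 <= r < min(dim(V)).")
  }
  normV <- sqrt(sum(V^2))
  out <- withr::with_seed(seed, {
    W <- matrix(stats::runif(nrow(V) * r), nrow(V), r) * sqrt(mean(V) / r)
    H <- matrix(0, r, ncol(V))
    residuals <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      H <- nnls_bpp(crossprod(W), crossprod(W, V))
      W <- t(nnls_bpp(tcrossprod(H), tcrossprod(H, V)))
      res <- sqrt(sum((V - W %*% H)^2)) / normV
      residuals <- c(residuals, res)
      if (is.finite(prev) && (prev - res) < tol * max(prev, 1e-12)) {
        converged <- TRUE
        break
      }
      # revive dead components: a zero basis column (or zero coefficient row)
      # contributes nothing, so reseeding it leaves the residual unchanged
      # while letting the next iteration recruit it.
      dead <- colSums(W) == 0 | rowSums(H) == 0
      if (any(dead)) {
        W[, dead] <- matrix(stats::runif(nrow(V) * sum(dead)), nrow(V)) *
          sqrt(mean(V) / r)
        H[dead, ] <- 0
      }
      prev <- res
    }
    list(W = W, H = H, residuals = residuals, res = res, converged = converged)
  })
  W <- out$W; H <- out$H
  residuals <- out$residuals; res <- out$res; converged <- out$converged
  if (!converged) {
    rlang::warn(sprintf("NMF did not converge within %d iterations (residual %.3g).",
                        max_iter, res))
  }
  structure(
    list(W = W, H = H, r = r, seed = seed, fit_error = res,
         residuals = residuals, converged = converged, n_iter = length(residuals)),
    class = "ictal_nmf"
  )
}

#' @export
print.ictal_nmf <- function(x, ...) {
  cat(sprintf("<ictal_nmf> rank %d, fit_error %.4g (%d iterations%s)\n",
              x$r, x$fit_error, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Glance at an NMF fit
#' @param x An `ictal_nmf`.
#' @param ... Unused.
#' @return One-row tibble with `rank`, `fit_error`, `n_iter`, `converged`.
#' @export
glance.ictal_nmf <- function(x, ...) {
  tibble::tibble(rank = x$r, fit_error = x$fit_error, n_iter = x$n_iter,
                 converged = x$converged)
}

# Greedy one-to-one matching of basis vectors by cosine similarity; returns
# the mean similarity of the matched pairs.
match_bases_cosine <- function(W1, W2) {
  norm1 <- sqrt(colSums(W1^2))
  norm2 <- sqrt(colSums(W2^2))
  norm1[norm1 == 0] <- 1
  norm2[norm2 == 0] <- 1
  S <- crossprod(sweep(W1, 2, norm1, "/"), sweep(W2, 2, norm2, "/"))
  r <- ncol(W1)
  sims <- numeric(r)
  for (k in seq_len(r)) {
    ij <- which(S == max(S), arr.ind = TRUE)[1, ]
    sims[k] <- S[ij[1], ij[2]]
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  mean(sims)
}

#' Select the NMF rank by cross-run stability
#'
#' For each candidate rank, fits `n_runs` seeded factorizations from
#' different random initializations, matches basis vectors across every pair
#' of runs by greedy maximum cosine similarity, and scores the rank by the
#' mean matched similarity. The selected rank is the largest one that still
#' factorizes reproducibly (stability at least `stable_tol`): because every
#' strictly positive matrix has a trivially stable mean-like leading
#' component, small ranks are always near-perfectly stable, and the
#' informative signal is the stability cliff just past the true rank.
#'
#' The selection is flagged low-confidence when the data carry no clear
#' low-rank structure: either every rank scores within `spread_tol` of the
#' others, or no cliff of at least `drop_tol` follows the chosen rank. In
#' the no-qualifying-rank case the smallest candidate is returned with a
#' warning.
#'
#' @param V Nonnegative matrix.
#' @param rank_range Integer vector of candidate ranks, each in
#'   `[2, min(dim(V)) - 1]`.
#' @param n_runs Seeded runs per rank (>= 2; default 20).
#' @param seed Integer base seed.
#' @param stable_tol Minimum cross-run stability for a rank to qualify
#'   (default 0.98).
#' @param drop_tol Minimum stability drop after the chosen rank required for
#'   a confident call (default 0.1).
#' @param spread_tol Minimum stability spread across ranks for a confident
#'   call (default 0.05).
#' @param ... Passed to [nmf_factorize()].
#' @return A list of class `ictal_rank_selection`: `rank`, `scores` (tibble
#'   with `rank`, `stability`), `low_confidence` (logical warning flag).
#' @export
select_rank_stability <- function(V, rank_range = 2:6, n_runs = 20L, seed = 1L,
                                  stable_tol = 0.98, drop_tol = 0.1,
                                  spread_tol = 0.05, ...) {
  if (n_runs < 2) rlang::abort("Stability is undefined for fewer than 2 runs.")
  if (any(rank_range < 2) || any(rank_range >= min(dim(V)))) {
    rlang::abort("rank_range must lie within [2, min(dim(V)) - 1].")
  }
  rank_range <- sort(rank_range)
  scores <- vapply(rank_range, function(r) {
    Ws <- lapply(seq_len(n_runs), function(run) {
      suppressWarnings(nmf_factorize(V, r, seed = seed + 1000L * r + run, ...)$W)
    })
    pairs <- utils::combn(n_runs, 2)
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      match_bases_cosine(Ws[[pairs[1, p]]], Ws[[pairs[2, p]]])
    }, numeric(1)))
  }, numeric(1))

  low_confidence <- FALSE
  qualifying <- which(scores >= stable_tol)
  if (length(qualifying) == 0) {
    rlang::warn("No rank factorizes reproducibly; returning the smallest candidate.")
    chosen_idx <- 1L
    low_confidence <- TRUE
  } else {
    chosen_idx <- max(qualifying)
  }
  if (max(scores) - min(scores) < spread_tol) {
    rlang::warn("Stability is flat across ranks: no rank is clearly preferred.")
    low_confidence <- TRUE
  } else if (chosen_idx < length(rank_range) &&
             scores[chosen_idx] - scores[chosen_idx + 1] < drop_tol) {
    rlang::warn(sprintf(
      "No stability cliff after rank %d (drop %.3f < %.3f): structure is weak.",
      rank_range[chosen_idx], scores[chosen_idx] - scores[chosen_idx + 1], drop_tol
    ))
    low_confidence <- TRUE
  }
  structure(
    list(rank = rank_range[chosen_idx],
         scores = tibble::tibble(rank = rank_range, stability = scores),
         low_confidence = low_confidence),
    class = "ictal_rank_selection"
  )
}

#' @export
print.ictal_rank_selection <- function(x, ...) {
  cat(sprintf("<ictal_rank_selection> chosen rank %d%s\n", x$rank,
              if (x$low_confidence) " (low confidence)" else ""))
  print(x$scores)
  invisible(x)
}

#' Reconstruct and renormalize the denoised connectivity matrix
#'
#' Computes `V* = W x H` and renormalizes every frequency-band block of every
#' window to sum 1, so that differences in reconstruction accuracy cannot
#' affect downstream distances. A whole-vector mode (the entire column summed
#' to 1) is available for comparison.
#'
#' @param model An `ictal_nmf`.
#' @param band_index Integer vector mapping features to bands.
#' @param mode `"band"` (default): each band block sums to 1; `"whole"`: the
#'   entire column sums to 1.
#' @return The renormalized nonnegative matrix `V*`, with a `band_index`
#'   attribute.
#' @export
denoise_reconstruct <- function(model, band_index, mode = c("band", "whole")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ictal_nmf"))
  if (length(band_index) != nrow(model$W)) {
    rlang::abort("`band_index` does not match the model's feature dimension.")
  }
  V_star <- model$W %*% model$H
  V_star <- if (mode == "band") {
    renormalize_blocks(V_star, band_index)
  } else {
    cs <- colSums(V_star)
    if (any(cs <= 0)) {
      rlang::abort(sprintf("Window %d reconstructs to all zero.", which(cs <= 0)[1]))
    }
    sweep(V_star, 2, cs, "/")
  }
  attr(V_star, "band_index") <- band_index
  V_star
}
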