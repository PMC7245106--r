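# Relating seizure dissimilarities to inter-seizure times: temporal distance
# matrices, one-tailed Mantel tests with Spearman correlation, BH-FDR across
# patients, and timescale-scanned temporal correlation patterns.

upper_tri_vec <- function(m) m[upper.tri(m)]

# Spearman rho between two vectors, average ranks for ties.
spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

#' Temporal distance matrix
#'
#' @param times Sorted seizure onset times in fractional days since the
#'   first seizure (`times[1] == 0`).
#' @return Symmetric, zero-diagonal matrix of class `ictal_dissim` holding
#'   `|t_i - t_j|` in days, with a `times` attribute. Duplicate onset times
#'   are allowed (distance 0) but flagged with a warning.
#' @export
temporal_distances <- function(times) {
  if (is.unsorted(times)) rlang::abort("`times` must be sorted.")
  if (abs(times[1]) > 1e-12) {
    rlang::abort("`times` must be measured in days since the first seizure (times[1] == 0).")
  }
  if (anyDuplicated(times)) {
    rlang::warn("Duplicate onset times: some temporal distances are exactly 0.")
  }
  TD <- abs(outer(times, times, "-"))
  attr(TD, "times") <- times
  class(TD) <- c("ictal_dissim", "matrix", "array")
  TD
}

# all permutations of seq_len(n) (n! rows); used for exhaustive Mantel
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' One-tailed Mantel test with Spearman correlation
#'
#' Tests the association between a seizure dissimilarity matrix and a
#' temporal distance matrix. Spearman's rho is computed between the
#' upper-triangle entries (average ranks for ties); significance comes from
#' permuting the rows and columns of one matrix jointly. The p-value is the
#' proportion of permuted correlations greater than or equal to the observed
#' one (one-sided, positive tail); an optional `(b + 1) / (n + 1)` estimator
#' is available. For 7 or fewer seizures, exhaustive enumeration of all `S!`
#' permutations replaces sampling, making small-cohort tests exact.
#'
#' @param D Seizure dissimilarity matrix.
#' @param TD Temporal distance matrix (same size, >= 4 seizures).
#' @param n_perm Number of sampled permutations (default 10000).
#' @param seed Integer seed for sampled permutations.
#' @param mode `"auto"` (exhaustive when `S <= 7`, else sampled),
#'   `"sampled"`, or `"exhaustive"` (errors if `S > 7`).
#' @param estimator `"literal"` (default): `p = b / n`; `"plus_one"`:
#'   `p = (b + 1) / (n + 1)`.
#' @return Object of class `ictal_mantel` with `rho`, `p`, `n_perm`,
#'   `mode`, `tail = "greater"`, `degenerate` (TRUE when an upper triangle
#'   is constant and rho is undefined).
#' @export
mantel_spearman <- function(D, TD, n_perm = 10000L, seed = 1L,
                            mode = c("auto", "sampled", "exhaustive"),
                            estimator = c("literal", "plus_one")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  Dm <- unclass(as.matrix(D))
  Tm <- unclass(as.matrix(TD))
  S <- nrow(Dm)
  if (!all(dim(Dm) == dim(Tm))) rlang::abort("Matrix sizes differ.")
  if (S < 4) rlang::abort("Need at least 4 seizures for a Mantel test.")
  x <- upper_tri_vec(Dm)
  y <- upper_tri_vec(Tm)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    res <- structure(
      list(rho = NA_real_, p = NA_real_, n_perm = 0L, mode = mode,
           tail = "greater", degenerate = TRUE),
      class = "ictal_mantel"
    )
    rlang::warn("Constant upper triangle: Spearman's rho is undefined.")
    return(res)
  }
  rx <- rank(x)
  rho_obs <- spearman(x, y)

  if (mode == "auto") mode <- if (S <= 7) "exhaustive" else "sampled"
  ut <- upper.tri(Tm)
  if (mode == "exhaustive") {
    if (S > 7) rlang::abort("Exhaustive mode supports at most 7 seizures (S! permutations).")
    perms <- all_permutations(S)
    rho_perm <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stats::cor(rx, rank(Tm[p, p][ut]))
    }, numeric(1))
    n_used <- nrow(perms)
  } else {
    rho_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(S)
        stats::cor(rx, rank(Tm[p, p][ut]))
      }, numeric(1))
    })
    n_used <- n_perm
  }
  b <- sum(rho_perm >= rho_obs - 1e-12)
  p_val <- if (estimator == "literal") b / n_used else (b + 1) / (n_used + 1)
  structure(
    list(rho = rho_obs, p = p_val, n_perm = n_used, mode = mode,
         tail = "greater", degenerate = FALSE),
    class = "ictal_mantel"
  )
}

#' @export
print.ictal_mantel <- function(x, ...) {
  if (x$degenerate) {
    cat("<ictal_mantel> degenerate (constant upper triangle)\n")
  } else {
    cat(sprintf("<ictal_mantel> rho = %.3f, one-tailed p = %.4g (%s, %d permutations)\n",
                x$rho, x$p, x$mode, x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.ictal_mantel <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p, n_perm = x$n_perm,
                 mode = x$mode, tail = x$tail, degenerate = x$degenerate)
}

#' @export
glance.ictal_mantel <- function(x, ...) tidy(x)

#' Benjamini-Hochberg FDR correction across patients
#'
#' @param p Numeric vector of Mantel p-values (one per patient), in \[0, 1\].
#'   `NA` entries (degenerate tests) are excluded from the correction.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @return Tibble with `p`, `p_adjusted`, `significant`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) rlang::abort("No p-values supplied.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p-values must lie in [0, 1].")
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj,
                 significant = !is.na(adj) & adj < alpha)
}

#' Temporal correlation pattern
#'
#' Scans the Spearman correlation between seizure dissimilarities and
#' temporal distances over timescales `T`, using only seizure pairs whose
#' temporal distance is at most `T`. `T` runs from `step` up to the largest
#' temporal distance in steps of `step` (default 0.25 d). A timescale is
#' masked if fewer than `min_pairs` pairs fall within it, or if no new pairs
#' were added relative to the previous grid point. The last valid timescale
#' includes every pair and reproduces the global Mantel rho.
#'
#' @param D Seizure dissimilarity matrix.
#' @param TD Temporal distance matrix.
#' @param step Timescale grid step in days (default 0.25).
#' @param min_pairs Minimum number of seizure pairs per timescale
#'   (default 7).
#' @return A tibble of class `ictal_tcp` with columns `timescale`,
#'   `n_pairs`, `new_pairs`, `valid`, `rho`; `rho` is `NA` where masked.
#'   Warns and returns an all-masked pattern when no timescale reaches
#'   `min_pairs`.
#' @export
compute_tcp <- function(D, TD, step = 0.25, min_pairs = 7L) {
  Dm <- unclass(as.matrix(D))
  Tm <- unclass(as.matrix(TD))
  if (!all(dim(Dm) == dim(Tm))) rlang::abort("Matrix sizes differ.")
  x <- upper_tri_vec(Dm)
  y <- upper_tri_vec(Tm)
  grid <- seq(step, ceiling(max(y) / step) * step, by = step)
  tcp_from_pairs(x, y, grid, min_pairs)
}

# Core TCP computation on pair vectors (shared with the model simulations).
tcp_from_pairs <- function(diss, td, grid, min_pairs = 7L) {
  n_pairs <- vapply(grid, function(Tk) sum(td <= Tk), integer(1))
  new_pairs <- diff(c(0L, n_pairs))
  valid <- n_pairs >= min_pairs & new_pairs > 0L
  rho <- rep(NA_real_, length(grid))
  for (k in which(valid)) {
    sel <- td <= grid[k]
    if (stats::sd(diss[sel]) == 0 || stats::sd(td[sel]) == 0) {
      valid[k] <- FALSE
      next
    }
    rho[k] <- spearman(diss[sel], td[sel])
  }
  if (!any(valid)) {
    rlang::warn("No timescale has enough seizure pairs: the pattern is empty.")
  }
  out <- tibble::tibble(timescale = grid, n_pairs = n_pairs,
                        new_pairs = new_pairs, valid = valid, rho = rho)
  class(out) <- c("ictal_tcp", class(out))
  out
}

#' @export
tidy.ictal_tcp <- function(x, ...) tibble::as_tibble(unclass(x))

#' Mean squared error between two temporal correlation patterns
#'
#' @param observed,simulated `ictal_tcp` tibbles on the same timescale grid.
#' @return Mean squared difference of `rho` over mutually valid timescales.
#' @export
tcp_mse <- function(observed, simulated) {
  if (nrow(observed) != nrow(simulated) ||
      any(abs(observed$timescale - simulated$timescale) > 1e-9)) {
    rlang::abort("Temporal correlation patterns are on different timescale grids.")
  }
  both <- observed$valid & simulated$valid
  if (!any(both)) rlang::abort("No mutually valid timescales.")
  mean((observed$rho[both] - simulated$rho[both])^2)
}
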