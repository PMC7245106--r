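# Per-patient end-to-end orchestration: connectivity -> NMF denoising ->
# dissimilarities -> temporal statistics -> dynamics classification.

#' Run the full per-patient analysis
#'
#' Sequences every stage on one patient's seizures: assemble the cohort
#' connectivity matrix, denoise it by NMF (stability rank selection unless a
#' rank is given), reconstruct and renormalize, compute the DTW seizure
#' dissimilarity matrix and the temporal distance matrix, run the one-tailed
#' Mantel test, compute the temporal correlation pattern, scan the model
#' grid, and classify the dynamics.
#'
#' @param seizures List of `ictal_cts` (one per seizure) or an
#'   `ictal_cohort` from [simulate_cohort()].
#' @param times Seizure onset times in days since the first seizure
#'   (taken from the cohort if omitted).
#' @param rank NMF rank; `NULL` (default) selects it by stability over
#'   `rank_range`.
#' @param rank_range Candidate ranks for stability selection (default 2:6).
#' @param n_runs Stability runs per rank (default 10).
#' @param n_perm Mantel permutations (default 10000).
#' @param n_sims Model simulations per grid cell (default 1000).
#' @param mse_threshold Good-match threshold (default 0.02185).
#' @param step,min_pairs Timescale grid parameters (defaults 0.25 d, 7).
#' @param min_seizures Inclusion threshold (default 6); cohorts with fewer
#'   seizures error unless `allow_few = TRUE`.
#' @param allow_few Permit fewer than `min_seizures` seizures.
#' @param seed Integer seed governing NMF, Mantel sampling and model
#'   simulations.
#' @return Object of class `ictal_patient_run` with elements `V`, `nmf`,
#'   `rank_selection`, `V_star`, `dissimilarity`, `temporal_distance`,
#'   `mantel`, `tcp`, `likelihoods`, `dynamics`, `config`.
#' @export
run_patient <- function(seizures, times = NULL, rank = NULL, rank_range = 2:6,
                        n_runs = 10L, n_perm = 10000L, n_sims = 1000L,
                        mse_threshold = 0.02185, step = 0.25, min_pairs = 7L,
                        min_seizures = 6L, allow_few = FALSE, seed = 1L) {
  if (inherits(seizures, "ictal_cohort")) {
    if (is.null(times)) times <- seizures$times
    seizures <- seizures$seizures
  }
  if (is.null(times)) rlang::abort("`times` are required when `seizures` is a plain list.")
  S <- length(seizures)
  if (S != length(times)) rlang::abort("One onset time per seizure is required.")
  if (S < min_seizures && !allow_few) {
    rlang::abort(sprintf(
      "Only %d seizures; at least %d are required for the analysis (set allow_few = TRUE to override).",
      S, min_seizures
    ))
  }

  cohort <- assemble_cohort_matrix(seizures)
  rank_selection <- NULL
  if (is.null(rank)) {
    rank_selection <- suppressWarnings(
      select_rank_stability(cohort$V, rank_range = rank_range,
                            n_runs = n_runs, seed = seed)
    )
    rank <- rank_selection$rank
  }
  nmf <- suppressWarnings(nmf_factorize(cohort$V, rank, seed = seed))
  V_star <- denoise_reconstruct(nmf, cohort$band_index)

  ids <- unique(cohort$windows$seizure_id)
  denoised <- lapply(ids, function(id) {
    connectivity_ts(V_star[, cohort$windows$seizure_id == id, drop = FALSE],
                    cohort$band_index, seizure_id = id)
  })
  D <- dissimilarity_matrix(denoised, ids = ids)
  TD <- temporal_distances(times)
  dimnames(TD) <- dimnames(D)
  mantel <- mantel_spearman(D, TD, n_perm = n_perm, seed = seed,
                            mode = if (S <= 7) "exhaustive" else "sampled")
  tcp <- compute_tcp(D, TD, step = step, min_pairs = min_pairs)
  likelihoods <- likelihood_scan(tcp, times, n_sims = n_sims,
                                 mse_threshold = mse_threshold, step = step,
                                 min_pairs = min_pairs, seed = seed)
  dynamics <- classify_dynamics(likelihoods)

  structure(
    list(
      V = cohort$V, windows = cohort$windows, band_index = cohort$band_index,
      nmf = nmf, rank_selection = rank_selection, V_star = V_star,
      dissimilarity = D, temporal_distance = TD, mantel = mantel, tcp = tcp,
      likelihoods = likelihoods, dynamics = dynamics,
      config = list(rank = rank, n_perm = n_perm, n_sims = n_sims,
                    mse_threshold = mse_threshold, step = step,
                    min_pairs = min_pairs, seed = seed)
    ),
    class = "ictal_patient_run"
  )
}

#' @export
print.ictal_patient_run <- function(x, ...) {
  cat(sprintf(
    "<ictal_patient_run> %d seizures | NMF rank %d | Mantel rho %.3f (p = %.4g) | dynamics: %s\n",
    nrow(x$dissimilarity), x$config$rank, x$mantel$rho, x$mantel$p, x$dynamics$class
  ))
  invisible(x)
}

#' One-row summary of a patient run
#' @param x An `ictal_patient_run`.
#' @param ... Unused.
#' @return Tibble with the headline quantities.
#' @export
glance.ictal_patient_run <- function(x, ...) {
  tibble::tibble(
    n_seizures = nrow(x$dissimilarity),
    rank = x$config$rank,
    rho = x$mantel$rho,
    p_value = x$mantel$p,
    L_l = x$likelihoods$L_l,
    L_c = x$likelihoods$L_c,
    L_lc = x$likelihoods$L_lc,
    L_n = x$likelihoods$L_n,
    dynamics = x$dynamics$class
  )
}

#' Persist a patient run as plain-text artifacts
#'
#' Writes the dissimilarity and temporal distance matrices, the temporal
#' correlation pattern, and a JSON summary (Mantel statistics, likelihood
#' table, classification with rationale) under one directory.
#'
#' @param run An `ictal_patient_run`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_patient_run <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(run$dissimilarity, file.path(path, "dissimilarity.csv"))
  write_matrix_csv(run$temporal_distance, file.path(path, "temporal_distance.csv"))
  write_tcp_csv(run$tcp, file.path(path, "tcp.csv"))
  jsonlite::write_json(
    list(
      mantel = list(rho = run$mantel$rho, p = run$mantel$p,
                    n_perm = run$mantel$n_perm, mode = run$mantel$mode),
      likelihoods = list(L_l = run$likelihoods$L_l, L_c = run$likelihoods$L_c,
                         L_lc = run$likelihoods$L_lc, L_n = run$likelihoods$L_n),
      likelihood_table = run$likelihoods$table,
      dynamics = list(class = run$dynamics$class,
                      rationale = run$dynamics$rationale),
      config = run$config
    ),
    file.path(path, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
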