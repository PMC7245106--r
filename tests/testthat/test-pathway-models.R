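test_that("basis functions match their closed forms", {
  expect_equal(f_linear(7), 1)
  expect_equal(f_linear(0), 0)
  expect_equal(f_circadian(0.25), 1, tolerance = 1e-12)
  expect_equal(f_circadian(0.5), 0, tolerance = 1e-12)
  for (t in c(0.1, 0.3, 0.9)) {
    expect_equal(f_circadian(t + 1), f_circadian(t), tolerance = 1e-12)
  }
})

test_that("simulated dissimilarities follow the combined-distance formula", {
  expect_equal(simulate_dissimilarity(c(0, 7), 1, 0, 0)[1, 2], 1)

  D <- simulate_dissimilarity(c(0, 0.25, 0.5), 0, 1, 0)
  expect_equal(D[1, 2], 1, tolerance = 1e-12)
  expect_equal(D[2, 3], 1, tolerance = 1e-12)
  expect_equal(D[1, 3], 0, tolerance = 1e-12)

  # the sine vanishes at integer days
  expect_equal(simulate_dissimilarity(c(0, 7), 1, 1, 0)[1, 2], 1,
               tolerance = 1e-12)

  Dn <- simulate_dissimilarity(c(0, 1, 2, 3), 0.5, 0.2, 0.3, seed = 4)
  expect_equal(Dn, t(Dn))
  expect_true(all(diag(Dn) == 0))
  expect_identical(Dn, simulate_dissimilarity(c(0, 1, 2, 3), 0.5, 0.2, 0.3, seed = 4))

  expect_error(simulate_dissimilarity(c(0, 1), 0, 0, 0), "positive")
  expect_error(simulate_dissimilarity(c(0, 1), -1, 0, 1), "nonnegative")
})

test_that("scaling all model weights leaves the correlation pattern unchanged", {
  times <- sample_seizure_times(10, 6, 0.2, seed = 5)
  TD <- temporal_distances(times)
  D1 <- simulate_dissimilarity(times, 0.5, 0.3, 0.2, seed = 6)
  D2 <- simulate_dissimilarity(times, 5, 3, 2, seed = 6)
  tcp1 <- compute_tcp(D1, TD)
  tcp2 <- compute_tcp(D2, TD)
  expect_equal(tcp1$rho, tcp2$rho, tolerance = 1e-12)
})

test_that("simulated pattern ensembles behave as their generating class dictates", {
  times <- sample_seizure_times(10, 6, 0.2, seed = 7)

  ens <- simulate_tcp_ensemble(times, 1, 0.5, 0, n_sims = 5, seed = 1)
  for (k in 2:5) expect_identical(ens[[k]]$rho, ens[[1]]$rho)

  lin <- simulate_tcp_ensemble(times, 1, 0, 0, n_sims = 1, seed = 1)[[1]]
  expect_true(all(abs(lin$rho[lin$valid] - 1) < 1e-12))

  noise <- simulate_tcp_ensemble(times, 0, 0, 1, n_sims = 200, seed = 2)
  rho_mat <- vapply(noise, function(x) x$rho, numeric(nrow(noise[[1]])))
  valid <- noise[[1]]$valid
  mean_rho <- rowMeans(rho_mat[valid, , drop = FALSE], na.rm = TRUE)
  expect_true(all(abs(mean_rho) < 0.1))
})

test_that("pattern MSE averages squared differences over mutually valid timescales", {
  times <- sample_seizure_times(10, 6, 0.2, seed = 8)
  TD <- temporal_distances(times)
  D <- simulate_dissimilarity(times, 1, 0, 0)
  tcp <- compute_tcp(D, TD)
  expect_equal(tcp_mse(tcp, tcp), 0)

  shifted <- tcp
  shifted$rho <- shifted$rho + 0.1
  expect_equal(tcp_mse(tcp, shifted), 0.01, tolerance = 1e-12)

  # masked timescales do not contribute
  masked <- shifted
  masked$rho[which(masked$valid)[1]] <- 99
  masked$valid[which(masked$valid)[1]] <- FALSE
  expect_equal(tcp_mse(tcp, masked), 0.01, tolerance = 1e-12)

  other_grid <- tcp[-1, ]
  expect_error(tcp_mse(tcp, other_grid), "grids")
})

test_that("the likelihood scan gives certainty to an exactly matching model", {
  times <- sample_seizure_times(12, 7, 0.2, seed = 9)
  TD <- temporal_distances(times)
  D <- simulate_dissimilarity(times, 1, 0, 0)
  tcp <- compute_tcp(D, TD)
  lik <- likelihood_scan(tcp, times, n_sims = 50, seed = 3)
  expect_equal(lik$L_l, 100)
  expect_true(all(lik$table$likelihood >= 0 & lik$table$likelihood <= 100))
  # likelihoods are percentages of good-match counts
  counts <- lik$table$likelihood * 50 / 100
  expect_true(all(abs(counts - round(counts)) < 1e-9))

  bad_grid <- model_grid()
  bad_grid <- bad_grid[bad_grid$class != "circadian", ]
  expect_error(likelihood_scan(tcp, times, grid = bad_grid, n_sims = 10),
               "lacks class")
})

test_that("classification rules fire as specified", {
  mk <- function(L_l, L_c, L_lc, L_n) {
    structure(list(L_l = L_l, L_c = L_c, L_lc = L_lc, L_n = L_n,
                   table = NULL, best = NULL, mse_threshold = 0.02185,
                   n_sims = 1000), class = "ictal_likelihoods")
  }
  # combined fails the 2x rule against linear only -> falls back to linear
  r1 <- classify_dynamics(mk(60, 5, 65, 10))
  expect_equal(r1$class, "linear")
  expect_true(any(grepl("Falling back", r1$rationale)))

  # best model does not beat noise
  r2 <- classify_dynamics(mk(15, 4, 12, 10))
  expect_equal(r2$class, "other/indeterminate")

  # neither separation rule satisfied
  r3 <- classify_dynamics(mk(40, 30, 50, 5))
  expect_equal(r3$class, "other/indeterminate")

  # dominant combined model
  r4 <- classify_dynamics(mk(20, 20, 80, 5))
  expect_equal(r4$class, "linear+circadian")

  # clear circadian
  r5 <- classify_dynamics(mk(10, 90, 95, 5))
  expect_equal(r5$class, "circadian")

  # decision is reproducible from the likelihoods alone
  expect_identical(classify_dynamics(mk(60, 5, 65, 10))$class, r1$class)
})
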