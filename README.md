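# ictalpath

Quantifying within-patient variability in seizure network evolution from
intracranial EEG.

## The problem

In focal epilepsy, a patient's seizures are often assumed to follow one
characteristic spatiotemporal pattern. Long presurgical iEEG recordings
suggest otherwise: the same brain can produce a repertoire of seizure
dynamics, and which variant occurs may depend on slowly drifting and daily
(circadian) modulatory processes. Knowing whether a patient's seizures
drift, oscillate, or vary at random matters for surgical planning, seizure
prediction, and closed-loop stimulation.

`ictalpath` implements a complete analysis chain for this question, aimed at
researchers working with multichannel ictal iEEG:

1. **Functional connectivity.** Each seizure is described by sliding-window
   (10 s window, 1 s step) **band-averaged coherence** in six frequency
   bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–80,
   high-gamma 80–150 Hz):

   C_ij = |Σ_f P_ij(f)|² / (Σ_f P_ii(f) · Σ_f P_jj(f)),

   with cross-/autospectra P from Welch's method (2 s segments, 1 s
   overlap). Upper-triangle edges are vectorized per band and L1-normalized
   to sum 1, so a seizure becomes a pathway through a normalized network
   space with 6·(n²−n)/2 features.

2. **NMF denoising.** The cohort matrix V (features × windows) is factorized
   as V ≈ W·H by alternating nonnegative least squares with block principal
   pivoting; the rank is chosen by cross-run stability, and the
   reconstruction V* = W·H is renormalized per band block.

3. **Seizure dissimilarity.** Pairs of seizures are aligned by dynamic time
   warping under L1 cost; the dissimilarity is the mean L1 distance over the
   warped path — zero for identical pathways traversed at different speeds,
   at most 12 (2 per band) for disjoint networks.

4. **Temporal statistics.** Dissimilarities are compared with inter-seizure
   intervals via a one-tailed Mantel permutation test (Spearman ρ) with
   BH-FDR across patients, and via **temporal correlation patterns**: ρ
   restricted to seizure pairs within timescale T, scanned in 0.25-day
   steps.

5. **Dynamics classification.** Candidate drift processes
   f_l(t) = t/7 (linear, slope one per week), f_c(t) = sin 2πt (circadian),
   and f_n ~ N(0,1) (noise) generate simulated dissimilarities
   Diss(i,j) = √((l·D_l)² + (c·D_c)² + (n·D_n)²) with D_x(i,j) =
   |f_x(t_i) − f_x(t_j)|. Each weight combination is simulated with fresh
   noise; the fraction of simulations whose temporal correlation pattern
   matches the observed one (MSE ≤ 0.02185) is that model's likelihood, and
   decision rules (best model must double the noise likelihood, the linear
   and circadian models must be clearly separated, a combined model must
   double both simpler ones) classify the patient as *linear*, *circadian*,
   *linear+circadian*, or *other/indeterminate*.

A synthetic-cohort generator (`simulate_cohort()`, `synthesize_ieeg()`)
plants known drift in the same normalized feature space, giving every stage
a ground truth without any clinical recordings.

## Worked example

Simulate a 12-seizure cohort over 7 days whose pathways drift linearly
(plus mild noise), then run the full analysis:

```r
library(ictalpath)

coh <- simulate_cohort(n_seizures = 12, monitoring_days = 7,
                       l_true = 1, c_true = 0, n_true = 0.1, seed = 42)
run <- run_patient(coh, rank = 3, n_perm = 10000, n_sims = 200, seed = 42)
glance(run)
#> # A tibble: 1 × 9
#>   n_seizures  rank   rho p_value   L_l   L_c  L_lc   L_n dynamics
#>        <int> <dbl> <dbl>   <dbl> <dbl> <dbl> <dbl> <dbl> <chr>
#> 1         12     3 0.809       0    24     0  20.5     0 linear
```

The Mantel correlation between seizure dissimilarity and inter-seizure time
is ρ = 0.809 with a permutation p-value below 1/10000: seizures closer in
time have more similar pathways. The likelihood table gives the linear model
L_l = 24% of good matches versus 0% for noise alone, and the decision trace
shows why the cohort is classified as linear:

```r
run$dynamics
#> <ictal_dynamics> linear
#>   - Best model: linear (L_max = 24.0%).
#>   - L_max = 24.0% >= 2 * L_n = 0.0%: outperforms noise alone.
#>   - L_l = 24.0% >= 2 * L_c = 0.0%: linear clearly beats circadian.
```

The drift is visible directly in the dissimilarity matrix — nearby seizures
(e.g. `sz04`/`sz05`, 0.17) are far more alike than distant ones
(`sz01`/`sz04`, 2.28):

```r
round(unclass(run$dissimilarity)[1:5, 1:5], 2)
#>      sz01 sz02 sz03 sz04 sz05
#> sz01 0.00 0.17 1.26 2.28 2.27
#> sz02 0.17 0.00 1.48 2.51 2.42
#> sz03 1.26 1.48 0.00 1.05 0.83
#> sz04 2.28 2.51 1.05 0.00 0.17
#> sz05 2.27 2.42 0.83 0.17 0.00
```

`autoplot()` methods display dissimilarity matrices, temporal correlation
patterns and likelihood surfaces; `mds_project()` + `plot_pathways()` draw
the 2D Sammon embedding of seizure pathways.

Published per-patient dissimilarities can be recomputed from archived NMF
factorizations exported to CSV (`read_nmf_deposit()`,
`dissimilarity_from_deposit()`); see the function documentation for the
expected layout.

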