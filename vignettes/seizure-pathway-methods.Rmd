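---
title: "Quantifying seizure pathway variability: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seizure pathway variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalpath)
```

`ictalpath` asks a simple clinical question with a layered statistical
machine: do a patient's seizures follow one stereotyped network evolution,
and if not, do the changes track time — slowly across the monitoring stay,
daily, both, or not at all? This vignette explains each layer, the
parameters that matter, and the choices made where the design was genuinely
open.

## 1. Seizures as pathways through network space

Each seizure is reduced to a multivariate time course of functional
connectivity. A 10-s window slides in 1-s steps over the preprocessed iEEG
(a seizure of duration $d$ seconds yields $\lfloor d-10\rfloor + 1$
windows). Per window and channel pair, band-averaged coherence is computed
in six bands:

$$C_{ij} \;=\; \frac{\bigl|\sum_{f=f_1}^{f_2} P_{ij}(f)\bigr|^2}
                   {\sum_{f=f_1}^{f_2} P_{ii}(f)\,\sum_{f=f_1}^{f_2} P_{jj}(f)},$$

with Welch cross- and autospectra (2-s segments, 1-s overlap). Summing
spectra over the band *before* forming the ratio makes $C_{ij}$ a coherence
"filtered in the frequency domain": it lies in $[0,1]$ by Cauchy–Schwarz and
is exactly 1 for proportional signals. The upper-triangle entries of each
band matrix are stacked (row-major edge order, bands delta → high-gamma) and
each band block is L1-normalized to sum 1. The normalization discards the
global coherence level and keeps only the *pattern*; it is also what makes
dissimilarity magnitudes comparable across patients with different electrode
counts.

Numerical choices here, stated once:

* **Band edges are half-open** $[f_1, f_2)$ on the discrete Welch grid. The
  band list (1–4–8–13–30–80–150 Hz) touches at its edges; half-open
  intervals assign each shared edge to exactly one band.
* **Welch segments use a Hann taper.** Any smooth taper would do; Hann is
  the standard default for coherence work.
* **Filtering** (1–150 Hz bandpass, 2-Hz-wide notches at the mains frequency
  and harmonics, all fourth-order zero-phase Butterworth) is implemented as
  analytically designed **cascaded biquads with steady-state initial
  conditions**. A 2-Hz-wide eighth-degree polynomial transfer function at
  fs = 512 Hz is numerically unusable (poles at $|z| \approx 0.995$ interact
  with coefficient rounding); second-order sections keep the response exact
  (verified $|H| \sim 10^{-9}$ at the notch frequency). Zero-phase filtering
  of a narrow notch still rings near the clip edges — an effect shared by
  every `filtfilt` implementation — so attenuation contracts are stated for
  seizure-length (tens of seconds) clips.
* **Degenerate inputs** error early: channels with zero variance (undefined
  autospectrum), all-zero band matrices (undefined normalization),
  missing-data gaps longer than `max_gap_s` (default 0.05 s; a per-seizure
  override exists because real recordings occasionally contain one longer
  documented gap), and sampling rates below 300 Hz (the 150-Hz band edge
  must stay below Nyquist).

## 2. Denoising by nonnegative matrix factorization

Window-to-window jitter in coherence would put a noise floor under every
seizure comparison. The cohort matrix $V$ (features × windows, all seizures
concatenated) is therefore approximated by $V \approx WH$ with
$W, H \ge 0$, and analyses use the renormalized reconstruction $V^*$.

The solver is alternating nonnegative least squares, each subproblem solved
exactly by block principal pivoting; the residual is monotone non-increasing
and the final relative Frobenius error is reported. Dead components (a basis
column that drops to zero) are reseeded — residual-neutral, since a zero
column contributes nothing — so a run cannot silently lose rank.

**Rank selection.** For each candidate rank the factorization is repeated
from `n_runs` random initializations; basis vectors are matched across run
pairs by greedy maximum cosine similarity and the rank is scored by the mean
matched similarity. The selected rank is the **largest rank that still
factorizes reproducibly** (stability ≥ 0.98). A pure argmax over stability
is degenerate: every strictly positive matrix has a mean-like leading
component, so rank 2 scores ≈ 1 on structured data and on noise alike. The
informative signal is the *cliff* — stability collapses one rank past the
true dimensionality — and the selection is flagged low-confidence when no
cliff of at least 0.1 follows the chosen rank, or when stability is flat
(spread < 0.05) across all candidates, as it is for unstructured data.

**Renormalization is per band block**, not per whole vector. The two
readings bound the maximum possible L1 distance between windows at 2
(whole-vector) versus 12 (per-band, 2 per band over six bands); observed
seizure dissimilarities above 2 in reference analyses are only consistent
with the per-band convention. A `mode = "whole"` switch retains the
alternative.

## 3. Dissimilarity by L1 dynamic time warping

Two seizures may traverse the same pathway at different speeds. Seizure
dissimilarity therefore aligns the two window sequences by dynamic time
warping — steps $(1,0)$, $(0,1)$, $(1,1)$ with unit weights, fixed
endpoints, no global band constraint, minimizing total L1 cost — and
averages the per-step L1 distance over the warped path. Properties that the
tests pin down:

* identical pathways, including uniformly time-dilated copies, have
  dissimilarity 0;
* constant pathways give exactly $\lVert u - v\rVert_1$;
* per-band contributions (mean warped distance within each band block) sum
  exactly to the total;
* the DP agrees with exhaustive enumeration of all admissible warping paths
  for short seizures.

The measure is *not* a metric — the triangle inequality may fail — and no
test assumes it. The step pattern is the common textbook default; since the
exact original configuration is not recoverable from a methods description,
the exhaustive-path oracle pins the implemented convention.

For display, windows are embedded in 2D by Sammon mapping on L1 distances,
initialized from classical MDS (duplicate windows are collapsed first so
zero distances cannot blow up the Sammon criterion). Whether a patient's
pathways form discrete clusters or a continuum is summarized by the gap
statistic (k-means on classical-MDS coordinates, 100 uniform reference sets,
one-standard-error rule, $k = 1$ allowed and reported as a "spectrum").

## 4. Temporal statistics

The temporal distance matrix holds $|t_i - t_j|$ in days. Association with
dissimilarity is tested by a one-tailed Mantel test: Spearman's ρ on the
upper triangles (average ranks for ties), with rows and columns of one
matrix permuted jointly; $p$ is the fraction of permuted correlations at
least as large as observed. Two deliberate details:

* the **literal estimator** $p = b/n$ is the default, with the smoothed
  $(b+1)/(n+1)$ variant available — the two differ only in whether the
  identity permutation is implicitly counted;
* for $S \le 7$ seizures all $S!$ permutations are **enumerated**, making
  small-cohort p-values exact rather than sampled.

Across patients, p-values are corrected by Benjamini–Hochberg FDR
(`stats::p.adjust`).

The **temporal correlation pattern** (TCP) scans ρ over timescales
$T = 0.25, 0.5, \dots$ days (up to the largest pairwise interval, grid
rounded up so the final point contains every pair). A timescale is masked
when fewer than 7 pairs fall within it or when no new pair was added
relative to the previous grid point (a plateau carries no new information).
By construction the last valid timescale reproduces the global Mantel ρ
exactly.

## 5. Generative models and classification

Three basis processes model how pathways drift: $f_l(t) = t/7$ (one unit per
week), $f_c(t) = \sin 2\pi t$ (period one day), $f_n \sim N(0,1)$ drawn once
per seizure. For weights $(l, c, n)$ the simulated dissimilarity is

$$\mathrm{Diss}(i,j) = \sqrt{[\,l D_l(i,j)]^2 + [\,c D_c(i,j)]^2 + [\,n D_n(i,j)]^2},
\qquad D_x(i,j) = |f_x(t_i) - f_x(t_j)|.$$

TCPs depend only on dissimilarity *ranks*, so only weight ratios matter; the
scan therefore covers the simplex $l + c + n = 1$ in steps of 0.1 (66
cells), which contains pure-noise, linear, circadian, and combined cells.
Each cell is simulated `n_sims` times with fresh noise; a simulation is a
*good match* when its TCP differs from the observed one by mean squared
error ≤ 0.02185 over mutually valid timescales (the threshold is the
reference fifth-percentile value; a cohort mode could recompute it, and the
argument is exposed). The likelihood of a model class is the best good-match
percentage among its cells.

Classification applies three auditable rules — recorded verbatim in a
rationale trace — requiring the best model to double the noise likelihood,
the linear and circadian models to be separated by a factor of two when one
of them wins, and a winning combined model to double both simpler models
(otherwise it falls back to the single comparable simpler model, or to
other/indeterminate when both are comparable). Ties in the argmax resolve
toward the simpler model, so a combined model never wins by equality.

## 6. What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` builds ground-truth cohorts: irregular onset times over
a monitoring window (uniform order statistics conditioned on a minimum gap —
the exact law of uniform sampling with a gap constraint, drawn without
rejection), a latent drift $g(t) = l\,t/7 + c\sin 2\pi t + n\,\varepsilon$,
and per-seizure connectivity time courses that mix two smooth endpoint
pathways $A, B$ window-by-window as $(1-\lambda)A_k + \lambda B_k$ with
folded Gaussian noise, renormalized per band.

* **Drift-to-mixing squash.** $g$ is mapped to $\lambda \in [0,1]$ by
  min–max **affine** rescaling by default. A logistic squash (available as
  an option) compresses large drifts; any strictly curved squash can swap
  near-tied pairwise distances, which destroys the exact rank agreement that
  noiseless linear cohorts are required to show (ρ = 1 at every valid
  timescale). The affine map preserves $|\Delta\lambda| \propto |\Delta g|$
  exactly and keeps the generator's advertised invariant true by
  construction.
* **Study conditions.** Recovery experiments use 12 seizures over 7 days
  with a 0.2-day minimum gap (sub-day spacing is what makes circadian
  structure identifiable), 15–30 windows per seizure, within-seizure noise
  SD 0.02, and latent noise $n = 0.1$. The combined condition uses
  $(l, c) = (2.5, 1)$: over a 7-day window the variance of the linear
  component is $l^2/12$ and of the circadian component $c^2/2$, so
  $l = \sqrt{6}\,c \approx 2.45c$ equalizes their contributions — neither
  component can mask the other.
* **Synthetic iEEG.** For the coherence calibration, every channel is one
  shared band-limited source plus independent noise *filtered to the same
  band*, at variance ratio `snr`. Shared spectral shape makes the in-band
  power ratio equal the variance ratio, giving the closed-form band
  coherence $\mathrm{snr}^2/(1+\mathrm{snr})^2$ (0.25 at snr = 1, 1 in the
  noise-free limit) that the estimator is tested against.

What passing these tests does **not** show about real data: the generator
produces stationary, smoothly mixing pathways with Gaussian perturbations.
Real seizures have nonstationary spectra, artifacts, electrode-dependent
geometry, state-dependent onset dynamics, and pathway changes that need not
be one-dimensional mixtures. The synthetic results validate the *machinery*
(estimators, alignments, statistics, decision rules), not any clinical
claim.

## 7. Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is sharply testable: 60-s clips at
512 Hz for coherence calibration; seizures of 2–6 windows for exhaustive DTW
enumeration; 500 (tests) or 200 (script) null replicates with 1000
permutations for Mantel calibration; 20 (tests) or 10 (script) replicated
cohorts with 200 simulations per grid cell for model recovery — the
reference configuration of 1000 simulations and 10,000 permutations remains
the default of `run_patient()`. Every stochastic step takes an explicit
seed, routed through `withr::with_seed`, so identical inputs give
bit-identical outputs; end-to-end reruns of `run_patient()` reproduce the
dissimilarity matrix exactly.

## 8. Known limitations

* Cross-patient comparison is limited to dissimilarity *magnitudes* (thanks
  to the L1 normalization); the feature spaces themselves are
  electrode-layout-specific and pathways cannot be compared across patients.
* The model family spans linear, circadian, and noise components only;
  multiday (weekly–monthly) cycles are outside the family and will surface
  as "other/indeterminate" or as poorly matched patterns.
* The stability rank rule assumes the candidate range brackets the true
  rank; if every candidate factorizes reproducibly the largest is taken, so
  an overly narrow range can truncate the rank.
* HDF5 and EDF+ annotation channels are not used; persistence is plain CSV/
  JSON bundles and a minimal 16-bit EDF reader/writer for signal clips.
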