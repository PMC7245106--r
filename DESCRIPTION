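Package: ictalpath
Title: Quantifying Within-Patient Variability in Seizure Network Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how a patient's seizures travel through the
    space of functional network configurations and how those pathways change
    over time. From multichannel ictal intracranial EEG the package computes
    sliding-window band-averaged coherence connectivity, denoises the cohort
    connectivity matrix by nonnegative matrix factorization with
    stability-based rank selection, measures pairwise seizure dissimilarity by
    L1 dynamic time warping, relates dissimilarities to inter-seizure times
    with Mantel permutation tests and timescale-scanned temporal correlation
    patterns, and classifies each patient's pathway dynamics as linear,
    circadian, or linear plus circadian by Monte-Carlo simulation. A synthetic
    cohort generator with planted drift provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    signal,
    MASS,
    cluster,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
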