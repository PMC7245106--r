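# Deposited NMF factorization (patient 931) — placeholder

This directory is the documented location for the archived per-patient NMF
factorization used by the worked-example acceptance test. The archive is
distributed separately (it is not shipped with the package); export the
patient's factorization to plain CSV and place four files here:

- `W.csv`          — basis matrix, features x rank (header row, numeric)
- `H.csv`          — coefficient matrix, rank x windows
- `windows.csv`    — one row per window, column `seizure_id`
- `band_index.csv` — one row per feature, column `band` (1..6)

`read_nmf_deposit()` validates the layout; `dissimilarity_from_deposit()`
reconstructs V* = W x H, renormalizes each band block, and computes the DTW
seizure dissimilarity matrix.
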