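# microstates

EEG microstate segmentation and information-theoretic analysis of the
resulting symbolic sequences, in R.

Resting-state EEG can be compressed into a sequence of *microstates*: a
small set of quasi-stable scalp potential topographies (conventionally
labeled A–D) that the multichannel signal visits one at a time. This
package implements the full pipeline from raw multichannel EEG to the
symbolic sequence, and a statistical toolbox for asking what kind of
stochastic process that sequence is: is it memoryless, first- or
second-order Markov? Are its dwell times geometric? Is its transition
matrix stationary and symmetric? Does it carry periodic information beyond
any Markov model?

It is aimed at EEG researchers analyzing resting-state recordings, and at
anyone working with categorical time series who needs likelihood-ratio
tests of Markov order, Markov surrogate data, or time-lagged mutual
information with confidence bands.

## The method

**Segmentation.** The global field power
`GFP_t = sd(x_t)` (population SD across electrodes of the
average-referenced sample) marks, at its local maxima, the moments of
highest topographic signal-to-noise. The topographies at GFP peaks are
clustered with the *modified (polarity-invariant) K-means* algorithm:
samples are assigned to the map with maximal squared spatial correlation
(so `x` and `-x` are the same state), and each cluster's map is updated to
the dominant eigenvector of the sum of outer products of its members — the
first principal component rather than the mean. Runs restart from random
peak samples; the run minimizing the electrode-corrected cross-validation
criterion

    CV = sigma^2 * ((n_ch - 1) / (n_ch - 1 - n_maps))^2

is kept. Back-fitting every sample to its best map (again by squared
correlation) yields the label sequence, and the global explained variance
(GEV) quantifies how much GFP-weighted variance the maps capture.

**Sequence statistics.** For a sequence with symbol counts `f_i`, pair
counts `f_ij`, etc., the package computes Shannon entropy (in nats),
the transition matrix, and six G tests (likelihood-ratio statistics,
asymptotically chi-square):

| test | null hypothesis | statistic |
|---|---|---|
| `test_markov0` | `P(X_{t+1} \| X_t) = P(X_{t+1})` | `G0 = 2 Σ f_ij log(n f_ij / f_i f_j)` |
| `test_markov1` | `P(X_{t+1} \| X_t, X_{t-1}) = P(X_{t+1} \| X_t)` | `G1a = 2 Σ f_ijk log(f_ijk f_j / f_ij f_jk)` |
| `test_geometric_lifetimes` | dwell times geometric with `q(k) = (1-T_ii) T_ii^{k-1}` | `G1b = 2 R_i Σ p_k log(p_k / q_k)` |
| `test_markov2` | order-2 conditional = order-3 conditional | `G2 = 2 Σ f_ijkl log(f_ijkl f_jk / f_ijk f_jkl)` |
| `test_stationarity` | per-block transitions homogeneous | Kullback's conditional-homogeneity G |
| `test_symmetry` | `f_ij` exchangeable with `f_ji` | `G4 = 2 Σ_{i≠j} f_ij log(2 f_ij / (f_ij + f_ji))` |

**Surrogates and autoinformation.** `synthesize_markov_chain()` builds
first-order Markov surrogates from the empirical `(π, T)` by inverse-CDF
sampling. The *autoinformation function* (AIF)

    I(k) = H(X_{t+k}) - H(X_{t+k} | X_t)

is the symbolic analogue of the autocorrelation function;
`empirical_aif()` estimates it by plug-in, `markov_aif()` evaluates the
closed form `I(k) = H(π) + Σ_i π_i Σ_j (T^k)_ij log (T^k)_ij` via
eigendecomposition, and `surrogate_confidence_band()` wraps data and
surrogate ensemble into a pointwise confidence band. Structure rising
above the band — e.g. periodic peaks tied to the alpha rhythm — is
information a first-order Markov model cannot explain.

I/O is deliberately minimal: a basic EDF/EDF+C reader and writer
(`read_edf()`, `write_edf()`), electrode coordinate files (`read_xyz()`),
and a batch pipeline (`run_pipeline()`, plus the thin CLI in
`inst/cli/microstates.R`). A synthetic-data module (`synth_maps()`,
`synth_labels()`, `synth_eeg()`) generates ground-truth EEG so every
stage is testable without any recording.

## Worked example

Synthesize a 2-minute, 30-channel recording from four planted
topographies whose hidden labels follow a diagonal-heavy Markov chain,
with amplitude-modulated 10 Hz carrier and white noise at SNR 5 — then
recover everything:

```r
library(microstates)

maps  <- synth_maps(layout, n_maps = 4, seed = 1)     # ground truth
truth <- synth_labels("markov", n = 30000, pi = pi0, T = T0, seed = 2)
rec   <- synth_eeg(maps, truth, fs = 250, snr = 5, seed = 3) |>
  bandpass_filter(1, 35)

seg <- modified_kmeans(rec, n_maps = 4, n_runs = 10, seed = 4)
seg
#> <microstate_segmentation> 4 maps, 30000 samples, 4172 GFP peaks
#>   total GEV = 0.795, CV = 1.171
#>   per-map GEV: 0.190 0.208 0.210 0.186

x <- label_sequence(seg$labels, n_states = 4, fs = 250)
glance(seg)[, c("gev_total", "entropy", "entropy_max")]
#>   gev_total entropy entropy_max
#> 1     0.795    1.38        1.39

markov_tests(x, block_len = 5000)
#>   test         state statistic    df  p_value
#> 1 markov0         NA  27919.       9 0
#> 2 markov1         NA     66.6     36 1.42e- 3
#> 3 markov2         NA    496.     144 3.17e-40
#> ...
#> 9 symmetry        NA      6.66     6 3.54e- 1

aif <- surrogate_confidence_band(x, k_max = 100, n_surr = 10, seed = 5)
aif
#> <microstate_aif> 100 lags, 10 surrogates, alpha = 0.01
#>   I(0) = 1.3843 nats; 49 lag(s) above the surrogate band
autoplot(aif)
```

Reading the output: four maps explain ~80% of the GFP-weighted variance;
the label entropy (1.38 nats) sits just below the four-symbol maximum
(log 4 = 1.39). The zero-order test rejects decisively (the chain has
strong self-transitions), and — although the *hidden* labels are Markov —
the *recovered* sequence rejects first-order Markovianity and shows AIF
peaks above the surrogate band: the rhythmic amplitude modulation imprints
periodic structure on the labels, the same signature reported for real
resting-state EEG. The symmetry test accepts, as the generating matrix is
nearly reversible.

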