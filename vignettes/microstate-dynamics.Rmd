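---
title: "Microstate segmentation and symbolic dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation and symbolic dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstates)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what its validation does and does not
demonstrate.

## The model

A multichannel EEG record is a matrix with time along the rows and
electrodes along the columns, in microvolts. The microstate model asserts
that, after average referencing, the instantaneous topography is well
approximated most of the time by one of a small number of fixed spatial
patterns, changing identity only every few tens of milliseconds. The
segmentation stage estimates those patterns and the hidden label sequence;
the analysis stage treats the label sequence as a categorical stochastic
process and interrogates its memory structure.

Two modeling commitments run through everything:

* **Polarity invariance.** A topography and its sign-flip are the same
  state. Assignment therefore uses squared spatial correlation, and
  cluster prototypes are first principal components (dominant
  eigenvectors of the within-cluster scatter), not means, which would
  cancel under polarity flips.
* **GFP-peak sampling.** Clustering uses only the topographies at local
  maxima of the global field power, where the topographic signal-to-noise
  ratio is highest; the full-length label sequence then comes from
  back-fitting every sample. Peaks-only labeling is intentionally not
  offered: downstream sequence statistics assume a regularly sampled
  process.

## Segmentation parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_maps` | 4 | maps | the field's canonical A–D decomposition; any integer ≥ 2 works |
| `n_runs` | 10 | restarts | the objective is non-convex; restarts from random GFP-peak samples |
| `maxerr` | 1e-6 | relative | convergence on the relative change of explained variance |
| `maxiter` | 500 | iterations | hard stop; convergence typically needs far fewer |
| band-pass | 1–40 Hz | Hz | default analysis band for resting-state EEG; the filtering example in the documentation uses 1–35 Hz, and both are common |

The run selected is the one minimizing the cross-validation criterion
`CV = sigma^2 * ((n_ch - 1)/(n_ch - 1 - n_maps))^2`, with `sigma^2` the
mean residual variance of the polarity-invariant fit computed from the
*unnormalized* peak topographies (per-peak residuals). The penalty term
corrects for electrode count, so CV is comparable across montages and
increases in `n_maps` at fixed fit quality.

Two details the literature leaves open, decided here:

* Peak topographies are normalized to unit norm before clustering. Under
  squared-correlation assignment this changes nothing about the
  assignment geometry, but it makes the cluster update a pure orientation
  estimate, insensitive to amplitude differences between peaks.
* Ties in back-fitting go to the lowest map index, and plateau GFP maxima
  report their first sample — both purely for determinism.

Canonical A–D ordering is non-interactive: either a user-supplied
permutation (`reorder_maps()`) or greedy `|correlation|` matching against
idealized geometric templates built from the electrode layout
(`template_maps()`: two diagonal gradients, an anterior–posterior
gradient, and a radial pattern). The templates are stylized, not
empirical group maps; for publication-grade ordering match against your
own reference set.

## The test battery

All six tests are likelihood-ratio (G) statistics compared to chi-square
upper tails; observed zero cells contribute zero (the `x log x -> 0`
convention), and no small-sample correction is applied. Marginals are
always taken over the same windows as the joint counts (the n-1
transition pairs, n-2 triplets, ...), which keeps each table internally
consistent.

The geometric lifetime statistic deserves a note. The natural divergence
`2 Σ p_k log(p_k/q_k)` between the empirical lifetime distribution and
the geometric law lacks a sample-size factor and would not converge to a
chi-square; the implementation multiplies by `R_i`, the number of runs of
the state, the count-weighted G form. The geometric model is renormalized
over the observed support `1..m`, and the degrees of freedom are `m - 1`.
Because the geometric parameter `T_ii` is itself estimated from the same
sequence, the test is mildly conservative; the type-I calibration below
shows it operates close to nominal level anyway. States with fewer than
two runs are skipped.

The stationarity test counts only within-block transitions (windows
crossing a block boundary are dropped, as is the trailing remainder), and
its degrees of freedom are `(r - 1)(n_s - 1) n_s` for `r` blocks. The
default block length of 5000 samples is 20 s at 250 Hz, long enough for
stable per-block transition estimates with four states.

One sign convention: divergences are implemented in the standard
non-negative Kullback–Leibler orientation, `Σ p log(p/q) ≥ 0`, so every
G statistic is non-negative.

Within one battery call (`markov_tests()`), a Benjamini–Hochberg adjusted
column is reported alongside the raw p-values; no correction is applied
inside any single test.

## Surrogates and autoinformation

Markov surrogates are built from the empirical symbol distribution `π`
and transition matrix `T` by inverse-CDF sampling, one uniform draw per
step. `π` is taken as the empirical symbol distribution rather than the
eigen-stationary distribution of `T`; the two differ by O(1/n) and the
choice keeps surrogate and data symbol frequencies aligned. The sampler
uses R's RNG, so a seed makes every surrogate ensemble reproducible.

The empirical AIF is the plug-in estimator from the joint histogram of
the `n - k` overlapping pairs at lag `k`. It is biased upward by
approximately `(n_s - 1)^2 / (2n)` nats; no correction is applied, and
because data and surrogates share `n`, the band comparison is
bias-matched. The analytic Markov AIF evaluates matrix powers through an
eigendecomposition in complex arithmetic, takes the real part after
checking the imaginary residue, and falls back to repeated multiplication
when the eigenvector matrix is ill-conditioned (reciprocal condition
number below 1e-12).

With the default 10 surrogates at `alpha = 0.01`, an empirical
`alpha/2` quantile is not supported by the ensemble, so the band is the
pointwise min–max envelope; with more than `1/alpha` surrogates it
switches to the empirical `(alpha/2, 1 - alpha/2)` quantiles. The
min–max band with a small ensemble is narrower than a true 99% interval,
which makes isolated band excursions at a handful of lags unremarkable;
sustained or periodic excursions are the meaningful signature.

## The synthetic-data generator

`synth_eeg()` builds `x_t = a_t * map[label_t] + noise_t`. The amplitude
`a_t` is a rectified sinusoid at the center of the carrier band (default
8–12 Hz, so 10 Hz), multiplied by a slow random envelope — band-limited
(0.2–0.8 Hz) standardized noise mapped through `max(0.25, 1 + 0.5 z)` —
emulating the strong amplitude modulation of posterior alpha rhythms.
Noise is spatially and temporally white, scaled so that the mean
per-channel signal variance over the noise variance equals `snr`.
Ground-truth maps are smooth Gaussian-process samples over the electrode
layout, orthogonalized against each other and the constant vector.

What the generator emulates: amplitude-modulated oscillatory GFP with
well-defined peaks, polarity-invariant topography dynamics, hidden label
processes that are Markov, semi-Markov (non-geometric dwell times),
higher-order, or periodic. What it does not emulate: colored or spatially
correlated noise, artifacts, volume-conduction lead fields, electrode
drift, or inter-subject map variability. Passing closure tests therefore
demonstrates correctness of the algorithms under the model's own
assumptions, not robustness to real-world EEG contamination.

One structural property of this generator is worth understanding, because
it mirrors real data: the carrier passes through zero twice per cycle, and
at those samples the topographic signal vanishes *regardless of the
nominal SNR*, so back-fitting assigns an essentially random label there.
Map recovery is insensitive to this (the affected samples are never GFP
peaks): matched absolute correlations exceed 0.95 at SNR 5. The
label-level closure — the recovered sequence's transition matrix matching
the generating one — is not: the noise-label fraction scales roughly as
`1/sqrt(snr)`, and a 0.05 max-abs agreement is reached around SNR 30–50
on top of a finite-sample floor of about 0.014 at 15 000 samples. The
test suite asserts the 0.05 closure at SNR 50 and a 0.15 bound at SNR 5.
A second consequence is scientifically pleasing: the rhythmic mislabeling
imprints carrier-periodic structure on the recovered sequence, so the AIF
of segmented synthetic EEG shows oscillatory peaks above the Markov band —
the same non-Markovian signature reported for real resting-state
recordings, arising here from a known mechanism.

## Validation design and problem sizes

The suite validates each statistic two ways: against brute-force
re-evaluations of the formulas from nested-loop count tables (agreement
to 1e-10), and against its sampling behavior under the null. Type-I
calibration uses 500 replicate first-order chains of 10^5 samples from a
diagonal-heavy four-state matrix; rejection counts at `alpha = 0.01` must
fall inside the exact binomial 99% acceptance region. Estimator
consistency uses single 10^6-sample chains (empirical vs analytic AIF
within 2e-3 nats; empirical vs generating transition matrix within 0.01).
These sizes make the whole suite run in well under a minute per heavy
block while leaving comfortable statistical margins.

EDF round-trips are validated against the 16-bit quantization bound: with
symmetric physical limits, the write–read error is at most half a digital
step, below `(phys_max - phys_min)/(2^16 - 1)`.

## Known limitations

* The EDF reader handles plain EDF and EDF+C with one sampling rate
  across retained signal channels; EDF+D, BDF, and annotation *parsing*
  (annotation channels are simply dropped) are out of scope.
* No temporal smoothing or minimum-duration constraint is applied to
  label sequences; if you need smoothed sequences, the statistics here
  apply unchanged but their interpretation differs.
* The chi-square reference distributions are asymptotic; for short
  sequences (a few thousand samples with four states) the geometric and
  second-order tests are the first to lose accuracy.
* `markov_aif()` assumes `π` is (close to) stationary for `T`; with a
  non-stationary `π` the closed form is still evaluated but is no longer
  a mutual information, and monotonicity in the lag is not guaranteed.
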