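---
title: "Denoising ECG signals with sparrow-search-tuned VMD and Hankel SVD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising ECG signals with sparrow-search-tuned VMD and Hankel SVD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmdenoise)
```

Electrocardiogram recordings pick up two kinds of interference that matter
for downstream analysis: *baseline wander* — slow (below roughly 1 Hz)
excursions of the isoelectric line caused by respiration and electrode
motion, which overlap the ST segment in frequency — and broadband noise
from muscle activity, electronics and mains coupling. `vmdenoise`
implements a decomposition-based pipeline that attacks both at once:

1. decompose the signal into band-limited modes (VMD);
2. identify the drift-carrying mode(s) by a mean-value criterion and set
   them aside;
3. keep only modes that correlate with the signal above an adaptive
   threshold;
4. clean each kept mode with Hankel-matrix SVD truncation;
5. sum the cleaned modes.

This vignette documents the model, every tunable that matters, the
synthetic data used to exercise the pipeline, the numerical choices, and —
importantly — what we measured about the method's limits.

## Variational mode decomposition

VMD poses decomposition as an optimisation: find $K$ modes $u_k$ with
centre frequencies $\omega_k$ minimising the summed bandwidth

$$\min_{\{u_k\},\{\omega_k\}}\;\sum_k \left\| \partial_t
\left[ \left(\delta(t) + \tfrac{j}{\pi t}\right) * u_k(t)\right]
e^{-j\omega_k t} \right\|_2^2
\quad\text{s.t.}\quad \sum_k u_k = f,$$

relaxed with a quadratic penalty $\alpha$ and a Lagrangian dual. The
frequency-domain ADMM solution alternates a Wiener-filter update

$$\hat u_k(\omega) \leftarrow
\frac{\hat f(\omega) - \sum_{i\ne k}\hat u_i(\omega) - \hat\lambda(\omega)/2}
{1 + 2\alpha(\omega - \omega_k)^2}$$

with a power-weighted centroid update of $\omega_k$, and (for dual step
$\tau > 0$) dual ascent on the reconstruction constraint. `vmd()` implements
this scheme in C++ on the positive half-spectrum; modes are returned sorted
by ascending centre frequency, so `imf1` is always the lowest-frequency
(drift-carrying) component.

Parameters and defaults:

| parameter  | meaning                              | default | unit |
|------------|--------------------------------------|---------|------|
| `k`        | number of modes                      | tuned   | —    |
| `alpha`    | bandwidth penalty (larger = narrower modes) | tuned | — (normalised frequency) |
| `tau`      | dual ascent step; 0 disables the exact-reconstruction constraint | 0 | — |
| `tol`      | convergence tolerance on summed relative mode change | 1e-7 | — |
| `max_iter` | ADMM iteration cap                   | 500     | —    |
| `init`     | centre-frequency initialisation      | uniform | —    |

`tau = 0` is the right default for denoising: with the constraint active,
broadband noise is forced back into the modes. The cost is that the mode
sum is a *filtered* version of the input, not an exact reconstruction.

**Boundary handling.** The signal is mirror-extended by half its length on
each side (symmetric reflection, the convention of the reference VMD
implementations) and cropped after decomposition. Reflection leaves a
derivative kink at the record ends; the Wiener updates smooth that kink,
which shows up as a small reconstruction error concentrated in the first
and last few tens of samples. On the clean three-tone benchmark
(`gen_test_signal()`, 1 s at 1 kHz, $K=3$, $\alpha=2000$) this edge effect
fixes the relative $L_2$ reconstruction error at 5.04% — we verified the
value to seven digits against an independent port of the reference
algorithm, so it is a property of mirrored VMD at $\tau = 0$, not of this
implementation. Interior error is an order of magnitude smaller. An odd
(point-symmetric) reflection was tried and rejected: it distorts the
centre-frequency estimates of low-frequency modes.

## Choosing K and alpha: sparrow search on envelope entropy

Decomposition quality depends strongly on $(K, \alpha)$, so `tune_vmd()`
selects them automatically. The fitness of a candidate pair is the
*minimum envelope entropy* across the resulting modes: the Shannon entropy
of the normalised Hilbert-envelope,

$$E(u) = -\sum_i p_i \ln p_i, \qquad p_i = \frac{a_i}{\sum_j a_j},$$

with $a$ the analytic-signal envelope. A mode whose energy concentrates in
short bursts (QRS complexes) has a sparse envelope and low entropy; noise
scores near the maximum $\ln n$. Minimising the per-decomposition minimum
rewards parameter pairs that isolate at least one strongly structured mode.
A `aggregate = "mean"` variant is available.

The optimiser is a faithful sparrow search: producers, scroungers and
scouts re-assigned by fitness rank each iteration, positions clamped to
the box $K \in [2, 15]$, $\alpha \in [500, 5000]$ and rounded to integers
after *every* move so the objective is only evaluated at feasible points.
Defaults follow the usual ECG protocol (population 30, 15 iterations).
Because the role-update equations are not uniquely standardised in the
literature, we adopt the original formulation (producer fraction 0.2,
scout fraction 0.1, safety threshold 0.8) and expose all three. Ties in
fitness keep the earlier-found position; fitness values are memoised on
the integer lattice (a pure run-time optimisation — results are
unchanged). On 2-D test functions the implementation reaches the sphere
optimum below `1e-3` in 20/20 seeds (population 30, 100 iterations) and
matches a 140-point exhaustive grid on the tuning objective to within
0.001 nats.

## Mode selection

Two criteria partition the modes:

* **Baseline (mean-value) criterion.** Oscillatory modes average to ~0
  over a record; the lowest mode absorbs the DC and sub-hertz drift
  content, so a mode with $|\bar u_k|$ above a threshold is flagged as a
  drift carrier. The threshold is not prescribed anywhere we could follow,
  so the default is scale-aware and conservative: three times the absolute
  mean of the signal's residual about its linear trend, floored at
  0.02 mV (`default_mean_threshold()`); in practice the floor acts.
* **Interrelation (correlation) criterion.** Each remaining mode's
  product-moment correlation $\rho$ with the signal is compared with the
  adaptive threshold $\mu = \max\rho / (10\max\rho - 3)$; modes with
  $\rho \ge \mu$ are effective, the rest noise.

Design choices the formulas leave open, and how we resolved them:

* $\rho$ is computed against the signal *after* subtracting the flagged
  baseline modes. With a large wander left in, its power dominates the
  variance and dilutes every oscillatory mode's $\rho$ toward the
  threshold formula's singularity (see below); removing the drift estimate
  first is also the order the procedure describes.
* The threshold formula has a pole at $\max\rho = 0.3$ and exceeds
  $\max\rho$ itself on $(0.3, 0.4)$, where it would reject everything.
  `selection_threshold()` raises a diagnosable error at the pole and
  supports a fixed fallback (the pipeline default is $\mu = 0.1$).
* $\rho$ is compared *signed*, as the formula is written; an
  absolute-value comparison is available (`rho_mode = "absolute"`).
* Equality $\rho = \mu$ counts as effective, so a mode is never dropped on
  a floating-point tie.

## Hankel SVD denoising

Each effective mode is embedded in a near-square Hankel matrix
($p = \lfloor n/2\rfloor + 1$ rows, maximising subspace separability),
decomposed as $H = \sum_i \sigma_i u_i v_i^T$, truncated after the largest
gap $d_i = \sigma_i - \sigma_{i+1}$ of the singular-value difference
spectrum (earliest index on ties), and averaged back along anti-diagonals.
A clean sinusoid generates an exactly rank-2 Hankel matrix, a sum of $m$
incommensurate tones rank $2m$; the difference spectrum recovers these
orders exactly in our tests, and truncation gains 20+ dB on a 10 dB noisy
sinusoid. If the largest gap sits at the last position, there is no
visible noise floor and the mode passes through unchanged with a warning.

Sequences longer than 5000 samples are processed in 2048-sample windows
with 50% overlap and linear crossfades, bounding the $O(n^3)$ SVD cost;
each window selects its own order. Window length and threshold are
arguments of `svd_denoise()`.

## Synthetic data: what it emulates, what it does not

`gen_synthetic_ecg()` builds each beat from five Gaussian bumps (P, Q, R,
S, T) with textbook lead-II amplitudes and timings (R peak 1 mV, default
60 bpm), repeats it with 1 ms beat-to-beat timing jitter, and centres the
record at zero mean. It reproduces the quasi-periodicity and spectral
envelope of a resting ECG — which is what the mode-selection logic keys
on — but none of the morphology variation, arrhythmia, or heart-rate
variability of real recordings, so passing benchmarks here demonstrates
mechanism, not clinical performance. `gen_baseline_wander()` is the
standard corruption used in this literature: a 0.4 mV, 0.5 Hz sinusoid.
Its `offset` argument adds the DC electrode offset that real wander rides
on; the benchmark corruption (`corrupt_ecg()`) uses 0.2 mV. The offset
matters for honesty of the benchmark: a pure sinusoid with an integer
number of periods has exactly zero mean and would be invisible to the
mean-value criterion, whereas real drift is not zero-mean over any
analysis window. `add_noise_at_snr()` rescales a white Gaussian draw so
the realised SNR is exact. All generators are pure functions of
(parameters, seed).

Only sinusoidal-plus-offset wander and white noise are modelled; the
electrode-motion and muscle-artifact noise types of the reference
databases are out of scope.

## Measured behaviour and known limitations

Problem sizes used throughout the tests and the acceptance script: 10 s of
ECG at 360 Hz (3600 samples), 1 s of the three-tone signal at 1 kHz, 10
corruption seeds for the pipeline benchmark, 20 seeds for the optimiser
and SVD oracles.

On the standard benchmark (synthetic ECG + 0.4 mV/0.5 Hz wander with
0.2 mV offset + 10 dB white noise, input SNR ≈ −6.8 dB) the tuned
pipeline removes the wander almost completely — the correlation between
(input − output) and the injected drift is 0.88–0.93, and the output's
1 s running mean stays two orders of magnitude below the drift amplitude
— and gains a median ≈ +10 dB of SNR. Three mechanisms cap the absolute
output SNR near 3–4 dB on this benchmark, and users should understand
them before applying the method elsewhere:

* **The envelope-entropy landscape is nearly flat.** Across the whole
  $[2,15]\times[500,5000]$ box the fitness spans ≈ 0.3 nats on this
  signal class, and its minimum sits at small $K$: one wide mode holding
  all the QRS bursts is the sparsest-envelope solution. The optimiser
  finds that minimum correctly; it is just weakly related to denoising
  quality.
* **The correlation threshold truncates the signal band.** The selected
  effective modes span roughly 1.5–20 Hz; the synthetic ECG keeps ~5% of
  its energy above 18 Hz, and that loss alone caps the achievable SNR
  around 11–12 dB (an ideal 0.7–30 Hz brick-wall filter on the same input
  reaches ≈ 18 dB).
* **The difference spectrum has no noise floor to find in Wiener-filtered
  modes.** A mode carrying several beat harmonics has smoothly decaying
  singular-value pairs; the largest gap then falls *inside* the signal
  subspace and truncation discards 10–20% of genuine mode energy. This is
  the documented trade-off of pairing max-gap order selection with
  $\tau = 0$ VMD; on nearly mono-component modes (where the rank-2
  structure holds) the same rule is exact.

The flip side: on clean input the pipeline is close to identity
(correlation ≈ 0.94 at fixed parameters), and every stage is individually
verified against closed forms, brute force, or an independent
implementation. The acceptance script (`scripts/acceptance.R`) recomputes
all of the above from scratch.

## Worked example

```{r example, eval = FALSE}
library(vmdenoise)

ecg   <- gen_synthetic_ecg(fs = 360, duration = 10, seed = 1)
noisy <- corrupt_ecg(ecg, seed = 42)

report <- ecg_denoise(noisy, reference = ecg, seed = 1)
glance(report)          # k, alpha, partition sizes, SNR / MSE
tidy(report$selection)  # per-mode centre frequency, mean, rho, role
autoplot(report)        # input / denoised / reference overlay
```

A fixed-parameter run (`k = 11, alpha = 3194`) is deterministic without a
seed and convenient for regression tests; the tuned run is deterministic
given `seed`.
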