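# vmdenoise

Removal of baseline wander and broadband noise from single-channel ECG
recordings, for signal-processing researchers and engineers who need a
fully scriptable, reproducible denoising pipeline with ground-truth
evaluation built in.

## Method

The pipeline combines three ideas:

1. **Variational mode decomposition (VMD).** The signal is split into
   `K` band-limited intrinsic mode functions by the frequency-domain ADMM
   scheme: each mode is updated by a Wiener filter centred on its current
   centre frequency,

   `u_k(w) <- (f(w) - sum_{i!=k} u_i(w) - lambda(w)/2) / (1 + 2*alpha*(w - w_k)^2)`,

   and `w_k` moves to the power-weighted centroid of the mode spectrum.
   `alpha` controls mode bandwidth.

2. **Sparrow search over `[K, alpha]`.** A producer/scrounger/scout
   swarm minimises the envelope entropy of the sparsest mode
   (`-sum p_i log p_i` over the normalised Hilbert envelope) over the
   integer box `K in [2, 15]`, `alpha in [500, 5000]` (population 30,
   15 iterations by default).

3. **Mode selection + Hankel SVD.** Modes whose mean exceeds a threshold
   are removed as baseline-drift carriers; the rest are kept when their
   correlation with the (drift-removed) signal clears the adaptive
   threshold `mu = max(rho) / (10*max(rho) - 3)`; each kept mode is
   embedded in a near-square Hankel matrix, truncated at the largest gap
   of its singular-value difference spectrum, and averaged back. The
   output is the sum of the cleaned modes. With a clean reference,
   quality is scored as `SNR = 10*log10(sum x^2 / sum (x - xhat)^2)` dB
   and `MSE = mean((x - xhat)^2)`.

Everything is driven by seeds and pure generator functions, so every
number is bit-reproducible.

## Worked example

```r
library(vmdenoise)

ecg   <- gen_synthetic_ecg(fs = 360, duration = 10, seed = 1)  # clean reference
noisy <- corrupt_ecg(ecg, seed = 42)   # + 0.4 mV / 0.5 Hz wander + 10 dB noise

report <- ecg_denoise(noisy, reference = ecg, k = 11, alpha = 3194)
report
#> <denoise_report> k = 11, alpha = 3194; 3/11 modes effective
#>   SNR 3.086 dB (input -6.825 dB), MSE 0.012513 mV^2

tidy(report$selection)
#> # A tibble: 11 × 5
#>    mode  center_freq_hz     mean_mv    rho role
#>  1 imf1           0.261 0.198       NA     baseline
#>  2 imf2           5.13  0.000511     0.650 effective
#>  3 imf3          10.8   0.000116     0.633 effective
#>  4 imf4          16.2   0.0000513    0.516 effective
#>  5 imf5          55.2   0.00000441   0.130 noise
#>  ...
```

Reading the output: the lowest mode (0.26 Hz, mean 0.198 mV) is the
injected wander riding on its electrode offset and is dropped; the three
modes spanning ~5–16 Hz carry the ECG and are kept; everything above
~55 Hz is rejected as noise. The denoised signal gains ~10 dB over the
corrupted input (−6.8 → +3.1 dB against the clean reference), with the
drift essentially gone. Omit `k`/`alpha` (and pass `seed =`) to let the
sparrow search choose them; omit `reference` to denoise real data, where
the SNR/MSE fields stay `NA`.

Real recordings come in through `read_signal()` (CSV or WFDB format-212,
e.g. MIT-BIH records). A command-line front end with `denoise`,
`simulate` and `optimize` subcommands lives in `inst/cli/vmdenoise.R`.

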