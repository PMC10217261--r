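# Shared fixtures, all built in code at test time.

# clean three-tone benchmark signal: 6 / 55 / 180 Hz at fs = 1000, 1 s
eq1_clean <- function() gen_test_signal(fs = 1000, duration = 1, noise_sd = 0)

# its closed form, for machine-precision comparison
eq1_closed_form <- function(t) {
  sin(2 * pi * 6 * t) + 1.2 * cos(2 * pi * 55 * t) + 1.4 * sin(2 * pi * 180 * t)
}

# standard denoising benchmark: clean ECG + drift + 10 dB white noise
benchmark_pair <- function(seed) {
  ecg <- gen_synthetic_ecg(fs = 360, duration = 10, seed = seed)
  noisy <- corrupt_ecg(ecg, seed = seed + 500)
  list(clean = ecg, noisy = noisy)
}

benchmark_drift <- function() {
  gen_baseline_wander(fs = 360, duration = 10, amplitude = 0.4, freq = 0.5,
                      offset = 0.2)
}

# dominant FFT peak frequencies of a signal, in Hz
spectral_peaks <- function(signal, n_peaks) {
  x <- signal$value
  n <- length(x)
  fs <- signal_fs(signal)
  amp <- Mod(fft(x))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) / n * fs
  sort(freqs[order(amp, decreasing = TRUE)[seq_len(n_peaks)]])
}
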