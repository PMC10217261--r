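#' Three-tone benchmark signal
#'
#' Generates the classic multi-tone test signal used to exercise mode
#' decomposition: `sin(2*pi*6*t) + 1.2*cos(2*pi*55*t) + 1.4*sin(2*pi*180*t)`
#' plus white Gaussian noise. The three tones at 6, 55 and 180 Hz are well
#' separated in frequency, so a correct decomposition at K = 3 recovers one
#' tone per mode.
#'
#' @param fs Sampling rate in Hz; must be at least 360 Hz (twice the highest
#'   tone) so the 180 Hz component is representable.
#' @param duration Duration in seconds.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in mV.
#'   The default 0.1 mV gives a mildly noisy signal; set 0 for the clean
#'   closed form.
#' @param seed Optional integer seed; given the same seed the output is
#'   bit-identical. The caller's RNG state is never touched.
#'
#' @return A signal tibble (`time`, `value`).
#' @examples
#' sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0)
#' @export
gen_test_signal <- function(fs, duration, noise_sd = 0.1, seed = NULL) {
  if (fs < 2 * 180) {
    abort(sprintf(
      "fs = %g Hz is below the Nyquist rate for the 180 Hz tone (need fs >= 360 Hz).",
      fs
    ))
  }
  if (duration <= 0) abort("`duration` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 6 * t) + 1.2 * cos(2 * pi * 55 * t) + 1.4 * sin(2 * pi * 180 * t)
  if (noise_sd > 0) {
    x <- x + with_seed_or_local(seed, rnorm(n, sd = noise_sd))
  }
  as_signal(x, fs = fs, label = "test-tones")
}

#' ECG beat morphology
#'
#' Parametric description of one heartbeat as five Gaussian bumps (P, Q, R,
#' S, T), each with an amplitude (mV), a width (Gaussian sigma, seconds) and
#' a time offset relative to the R peak (seconds). This is a deliberately
#' simple stand-in for real ECG morphology: it reproduces the quasi-periodic
#' P-QRS-T structure and realistic spectral content, not patient-specific or
#' pathological waveforms.
#'
#' Default amplitudes and timings follow textbook lead-II values: a 1 mV R
#' peak, small negative Q and S deflections, a low broad P wave 180 ms before
#' the R peak and a broad T wave 300 ms after it.
#'
#' @param heart_rate Heart rate in beats per minute.
#' @param amplitudes,widths,offsets Named numeric vectors over
#'   `c("P","Q","R","S","T")`: bump heights (mV), Gaussian sigmas (s) and
#'   centre offsets from the R peak (s).
#'
#' @return An object of class `ecg_morphology`.
#' @examples
#' ecg_morphology(heart_rate = 72)
#' @export
ecg_morphology <- function(heart_rate = 60,
                           amplitudes = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.25, T = 0.30),
                           widths     = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.045),
                           offsets    = c(P = -0.180, Q = -0.035, R = 0.000, S = 0.035, T = 0.300)) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(amplitudes, widths, offsets)) {
    if (!all(waves %in% names(v))) abort("amplitudes/widths/offsets must be named over P, Q, R, S, T.")
  }
  if (heart_rate <= 0) abort("`heart_rate` must be > 0.")
  if (any(widths[waves] <= 0)) abort("All wave widths must be > 0.")
  period <- 60 / heart_rate
  if (any(abs(offsets[waves]) >= period)) {
    abort("Wave offsets must lie within one beat period.")
  }
  structure(
    list(
      heart_rate = heart_rate,
      amplitudes = amplitudes[waves],
      widths = widths[waves],
      offsets = offsets[waves]
    ),
    class = "ecg_morphology"
  )
}

#' @export
print.ecg_morphology <- function(x, ...) {
  cat(sprintf("<ecg_morphology> %g bpm\n", x$heart_rate))
  print(tibble(
    wave = names(x$amplitudes),
    amplitude_mV = unname(x$amplitudes),
    width_s = unname(x$widths),
    offset_s = unname(x$offsets)
  ))
  invisible(x)
}

#' Synthetic quasi-periodic ECG
#'
#' Repeats the Gaussian-bump beat template of an [ecg_morphology()] at the
#' beat period, with small seeded beat-to-beat timing jitter, and centres the
#' record so its overall mean is zero (the isoelectric line then sits
#' slightly below zero, and the R peak rises the configured R amplitude above
#' it). Intended as a clean reference signal for denoising benchmarks where
#' the ground truth must be known exactly.
#'
#' @inheritParams gen_test_signal
#' @param morphology An [ecg_morphology()] object.
#' @param jitter_sd Standard deviation of the per-beat timing jitter in
#'   seconds (default 1 ms, well under one sample period at typical ECG
#'   sampling rates, so mean RR intervals stay at `60 / heart_rate`).
#'
#' @return A signal tibble (`time`, `value`).
#' @examples
#' ecg <- gen_synthetic_ecg(fs = 360, duration = 10, seed = 1)
#' @export
gen_synthetic_ecg <- function(fs, duration, morphology = ecg_morphology(),
                              jitter_sd = 0.001, seed = NULL) {
  if (fs <= 0) abort("`fs` must be > 0.")
  if (!inherits(morphology, "ecg_morphology")) {
    abort("`morphology` must be an `ecg_morphology` object.")
  }
  period <- 60 / morphology$heart_rate
  if (duration < 2 * period) abort("`duration` must cover at least 2 beats.")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  n_beats <- floor(duration / period)
  jitter <- if (jitter_sd > 0) {
    with_seed_or_local(seed, rnorm(n_beats, sd = jitter_sd))
  } else {
    numeric(n_beats)
  }
  ## R peaks at period/2, 3*period/2, ... so the first/last beats fit whole
  r_times <- (seq_len(n_beats) - 0.5) * period + jitter
  x <- numeric(n)
  for (b in seq_len(n_beats)) {
    for (w in names(morphology$amplitudes)) {
      a <- morphology$amplitudes[[w]]
      if (a == 0) next
      s <- morphology$widths[[w]]
      mu <- r_times[b] + morphology$offsets[[w]]
      ## Gaussian support is effectively +/- 6 sigma; skip the rest
      lo <- max(1L, floor((mu - 6 * s) * fs) + 1L)
      hi <- min(n, ceiling((mu + 6 * s) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + a * exp(-0.5 * ((t[idx] - mu) / s)^2)
    }
  }
  if (any(x != 0)) x <- x - mean(x)
  as_signal(x, fs = fs, label = "synthetic-ecg")
}

#' Sinusoidal baseline wander
#'
#' Models respiratory/electrode baseline drift as
#' `offset + amplitude * sin(2*pi*freq*t + phase)`. The defaults (0.4 mV at
#' 0.5 Hz) are the standard corruption used in ECG denoising benchmarks. A
#' nonzero `offset` models the DC electrode offset that real baseline wander
#' rides on; it is what makes drift-carrying decomposition modes detectable
#' by a mean-value criterion.
#'
#' @inheritParams gen_test_signal
#' @param amplitude Drift amplitude in mV.
#' @param freq Drift frequency in Hz; must be below `fs / 2`.
#' @param offset Constant offset in mV (default 0).
#' @param phase Initial phase in radians (default 0).
#'
#' @return A signal tibble (`time`, `value`).
#' @examples
#' bw <- gen_baseline_wander(fs = 360, duration = 10)
#' max(abs(bw$value)) # 0.4
#' @export
gen_baseline_wander <- function(fs, duration, amplitude = 0.4, freq = 0.5,
                                offset = 0, phase = 0) {
  if (fs <= 0) abort("`fs` must be > 0.")
  if (duration <= 0) abort("`duration` must be > 0.")
  if (freq >= fs / 2) {
    abort(sprintf("`freq` (%g Hz) must be below fs/2 (%g Hz).", freq, fs / 2))
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  as_signal(offset + amplitude * sin(2 * pi * freq * t + phase),
            fs = fs, label = "baseline-wander")
}

#' Add white Gaussian noise at a target SNR
#'
#' Draws white Gaussian noise and rescales the realised draw so that the
#' measured signal-to-noise ratio of `clean + noise` against `clean`
#' (see [snr_db()]) equals `snr_db` exactly.
#'
#' @param clean A signal tibble with nonzero power.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Optional integer seed (bit-reproducible noise).
#'
#' @return A signal tibble of the same length: `clean + noise`.
#' @examples
#' ecg <- gen_synthetic_ecg(fs = 360, duration = 10, seed = 1)
#' noisy <- add_noise_at_snr(ecg, snr_db = 10, seed = 2)
#' snr_db(ecg, noisy) # 10
#' @export
add_noise_at_snr <- function(clean, snr_db, seed = NULL) {
  clean <- validate_signal(clean, "clean")
  x <- clean$value
  px <- sum(x^2)
  if (px == 0) abort("`clean` is all zero: SNR is undefined.")
  z <- with_seed_or_local(seed, rnorm(length(x)))
  ## scale the realised draw so sum(noise^2) = sum(x^2) / 10^(snr/10) exactly
  target <- px / 10^(snr_db / 10)
  noise <- z * sqrt(target / sum(z^2))
  out <- clean
  out$value <- x + noise
  out
}
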