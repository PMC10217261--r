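#' Build a signal tibble from a numeric vector
#'
#' Every function in vmdenoise exchanges signals as plain tibbles with a
#' `time` column (seconds, starting at 0, uniformly spaced) and a `value`
#' column (millivolts). `as_signal()` wraps a bare numeric vector, or
#' validates a data frame that already has that shape. Sample `i` (1-based)
#' occurs at `t = (i - 1) / fs`.
#'
#' @param x Numeric vector of samples, or a data frame with `time` and
#'   `value` columns.
#' @param fs Sampling rate in Hz. Required when `x` is a numeric vector;
#'   when `x` is a data frame it is checked against the time column if given.
#' @param label Optional identifier stored in a `label` column when not `NULL`.
#'
#' @return A tibble with columns `time` and `value` (and `label` if supplied).
#' @examples
#' as_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), fs = 250)
#' @export
as_signal <- function(x, fs = NULL, label = NULL) {
  if (is.data.frame(x)) {
    sig <- validate_signal(x)
    if (!is.null(fs)) {
      fs_obs <- signal_fs(sig)
      if (abs(fs_obs - fs) > 1e-6 * fs) {
        abort(sprintf(
          "`fs` (%g Hz) disagrees with the spacing of the time column (%g Hz).",
          fs, fs_obs
        ))
      }
    }
    if (!is.null(label)) sig$label <- label
    return(sig)
  }
  if (!is.numeric(x)) abort("`x` must be a numeric vector or a data frame.")
  if (is.null(fs)) abort("`fs` is required when `x` is a bare numeric vector.")
  if (fs <= 0) abort("`fs` must be > 0.")
  n <- length(x)
  if (n < 2) abort("A signal needs at least 2 samples.")
  if (!all(is.finite(x))) abort("Signal samples must all be finite.")
  out <- tibble(time = (seq_len(n) - 1) / fs, value = as.numeric(x))
  if (!is.null(label)) out$label <- label
  out
}

#' Sampling rate of a signal tibble
#'
#' @param signal A signal tibble (see [as_signal()]).
#' @return Sampling rate in Hz, inferred from the spacing of `time`.
#' @export
signal_fs <- function(signal) {
  signal <- validate_signal(signal)
  1 / median(diff(signal$time))
}

#' @rdname signal_fs
#' @export
signal_values <- function(signal) {
  validate_signal(signal)$value
}

#' Duration of a signal tibble in seconds
#'
#' Defined as `n / fs` so that concatenating two segments adds their
#' durations (the last sample is followed by one implicit sample period).
#'
#' @inheritParams signal_fs
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) {
  signal <- validate_signal(signal)
  nrow(signal) / signal_fs(signal)
}

## Checks the signal contract: time + value columns, >= 2 finite samples,
## strictly uniform sampling (relative tolerance 1e-6 on the step).
validate_signal <- function(signal, arg = "signal") {
  if (!is.data.frame(signal)) {
    abort(sprintf("`%s` must be a data frame with `time` and `value` columns.", arg))
  }
  if (!all(c("time", "value") %in% names(signal))) {
    abort(sprintf("`%s` must have `time` and `value` columns.", arg))
  }
  if (nrow(signal) < 2) abort(sprintf("`%s` needs at least 2 samples.", arg))
  if (!all(is.finite(signal$value))) {
    abort(sprintf("`%s` contains non-finite sample values.", arg))
  }
  dt <- diff(signal$time)
  if (any(dt <= 0)) abort(sprintf("`%s` time column must be strictly increasing.", arg))
  step <- median(dt)
  if (max(abs(dt - step)) > 1e-6 * step) {
    abort(sprintf("`%s` is not uniformly sampled (use a resampler first).", arg))
  }
  as_tibble(signal)
}

## Accept either a signal tibble or a bare numeric vector; return the sample
## vector. Used by vector-first numeric helpers.
pull_values <- function(x, arg = "x") {
  if (is.data.frame(x)) validate_signal(x, arg)$value else as.numeric(x)
}

## Local RNG scope: functions that take a `seed` argument are pure in
## (arguments, seed) and never disturb the caller's RNG state.
with_seed_or_local <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), code)
}
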