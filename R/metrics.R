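#' Signal-to-noise ratio in decibels
#'
#' \deqn{\mathrm{SNR} = 10 \log_{10}\!\left(\frac{\sum_i x_i^2}
#'   {\sum_i (x_i - \tilde x_i)^2}\right)}
#' where `x` is the clean reference and `x~` the estimate. An estimate
#' identical to the reference has zero error power and is reported as
#' `Inf` (a perfect score), not an error.
#'
#' @param reference Clean reference: numeric vector or signal tibble with
#'   nonzero power.
#' @param estimate Estimate of the same length.
#' @return SNR in dB (`Inf` when `estimate` equals `reference`).
#' @examples
#' snr_db(c(1, 1), c(0, 0)) # 0 dB: error power equals signal power
#' @export
snr_db <- function(reference, estimate) {
  x <- pull_values(reference, "reference")
  y <- pull_values(estimate, "estimate")
  if (length(x) != length(y)) abort("`reference` and `estimate` must have equal length.")
  px <- sum(x^2)
  if (px == 0) abort("`reference` has zero power: SNR undefined.")
  pe <- sum((x - y)^2)
  if (pe == 0) return(Inf)
  10 * log10(px / pe)
}

#' Mean squared error
#'
#' \deqn{\mathrm{MSE} = \frac{1}{N}\sum_i (x_i - \tilde x_i)^2}
#'
#' @inheritParams snr_db
#' @return MSE in squared millivolts.
#' @examples
#' mse(c(1, 1), c(0, 0)) # 1
#' @export
mse <- function(reference, estimate) {
  x <- pull_values(reference, "reference")
  y <- pull_values(estimate, "estimate")
  if (length(x) != length(y)) abort("`reference` and `estimate` must have equal length.")
  mean((x - y)^2)
}
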