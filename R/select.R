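#' Interrelation number between two sequences
#'
#' The normalised cross-moment
#' \deqn{\rho_{xy} = \frac{\sum_n (x_n - \bar x)(y_n - \bar y)}
#'   {\left[\sum_n (x_n - \bar x)^2 \sum_n (y_n - \bar y)^2\right]^{1/2}}}
#' i.e. the product-moment correlation, always in \[-1, 1\]. Used to score
#' how much of the original signal each decomposition mode carries.
#'
#' @param x,y Numeric vectors (or signal tibbles) of equal length >= 2,
#'   each with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @examples
#' interrelation_number(1:10, (1:10)^2)
#' @export
interrelation_number <- function(x, y) {
  x <- pull_values(x, "x")
  y <- pull_values(y, "y")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("Need at least 2 samples.")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) abort("Zero-variance input: interrelation number undefined.")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Correlation threshold for effective-mode selection
#'
#' Computes the adaptive threshold
#' \deqn{\mu = \frac{\max \rho}{10 \max \rho - 3}}
#' from the per-mode interrelation numbers. The formula is only defined for
#' `max(rho) > 0.3` (the denominator changes sign at 0.3); below that the
#' decomposition correlates so weakly with the signal that the adaptive rule
#' has no meaning, and a fixed fallback threshold can be supplied instead.
#'
#' @param rho Numeric vector of per-mode interrelation numbers.
#' @param fallback Optional fixed threshold returned when
#'   `max(rho) <= 0.3`. With the default `NULL` that case is an error.
#' @return Threshold value \eqn{\mu}.
#' @examples
#' selection_threshold(c(0.2, 0.9, 0.4)) # 0.9 / 6 = 0.15
#' @export
selection_threshold <- function(rho, fallback = NULL) {
  if (length(rho) < 1 || !all(is.finite(rho))) {
    abort("`rho` must be a non-empty finite vector.")
  }
  m <- max(rho)
  if (m <= 0.3) {
    if (!is.null(fallback)) return(fallback)
    abort(paste0(
      sprintf("max(rho) = %.4g <= 0.3: the adaptive threshold max/(10*max - 3) ", m),
      "is undefined (non-positive denominator). Supply `fallback` (e.g. 0.1) ",
      "to use a fixed threshold."
    ))
  }
  m / (10 * m - 3)
}

#' Flag baseline-drift modes by the mean-value criterion
#'
#' Baseline wander is the only component expected to push a band-limited
#' mode's mean away from zero: oscillatory modes average out, while the
#' drift mode absorbs the DC/very-low-frequency content. Modes whose
#' absolute mean exceeds `mean_threshold` are flagged as drift carriers.
#'
#' @param fit A `vmd` object.
#' @param mean_threshold Threshold in mV. `NULL` (default) uses
#'   [default_mean_threshold()] on the decomposed signal.
#' @return Integer vector of flagged mode indices (possibly empty).
#' @export
flag_baseline_modes <- function(fit, mean_threshold = NULL) {
  stopifnot(inherits(fit, "vmd"))
  if (is.null(mean_threshold)) {
    mean_threshold <- default_mean_threshold(fit$signal$value)
  }
  unname(which(abs(colMeans(fit$modes)) > mean_threshold))
}

#' Default baseline mean threshold
#'
#' Scale-aware default for the mean-value drift criterion: three times the
#' absolute mean of the signal's residual about its linear trend, floored at
#' 0.02 mV. For any signal whose oscillatory content averages out (the usual
#' case) the floor is what acts; the data-driven term only raises the
#' threshold for pathologically asymmetric records.
#'
#' @param x Numeric vector or signal tibble.
#' @return Threshold in mV.
#' @export
default_mean_threshold <- function(x) {
  x <- pull_values(x)
  n <- length(x)
  trend <- stats::fitted(stats::lm.fit(cbind(1, seq_len(n)), x))
  max(0.02, 3 * abs(mean(x - trend)))
}

#' Partition VMD modes into baseline, effective and noise groups
#'
#' Implements the two-stage selection used in the denoising pipeline:
#'
#' 1. modes whose absolute mean exceeds `mean_threshold` are set aside as
#'    baseline-drift carriers ([flag_baseline_modes()]);
#' 2. each remaining mode's interrelation number with the original signal
#'    is computed ([interrelation_number()]), the adaptive threshold
#'    \eqn{\mu} is derived from their maximum ([selection_threshold()]),
#'    and modes with \eqn{\rho \ge \mu} are kept as effective, the rest
#'    rejected as noise.
#'
#' Equality counts as effective so a mode is never dropped on a
#' floating-point tie. By default the signed \eqn{\rho} is compared;
#' `rho_mode = "absolute"` compares \eqn{|\rho|} instead.
#'
#' @param fit A `vmd` object.
#' @param signal Signal the comparison is made against; defaults to the
#'   signal stored in `fit` (the decomposed one).
#' @param mean_threshold Baseline mean threshold in mV (`NULL` = default).
#' @param rho_mode Compare `"signed"` (default) or `"absolute"` correlation.
#' @param mu_fallback Fixed threshold used when `max(rho) <= 0.3`
#'   (see [selection_threshold()]); `NULL` makes that case an error.
#'
#' @return An object of class `mode_selection`: `baseline_idx`,
#'   `effective_idx`, `noise_idx` (disjoint, covering all modes), `rho`
#'   (per non-baseline mode, `NA` for baseline modes), `mu`, `mean_values`
#'   and `mean_threshold`. `tidy()` gives one labelled row per mode.
#' @examples
#' sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0, seed = 1)
#' sel <- select_modes(vmd(sig, k = 3, alpha = 2000))
#' tidy(sel)
#' @export
select_modes <- function(fit, signal = NULL, mean_threshold = NULL,
                         rho_mode = c("signed", "absolute"), mu_fallback = NULL) {
  stopifnot(inherits(fit, "vmd"))
  rho_mode <- match.arg(rho_mode)
  if (is.null(signal)) signal <- fit$signal
  signal <- validate_signal(signal)
  if (nrow(signal) != nrow(fit$modes)) {
    abort("`signal` must have the same length as the decomposed modes.")
  }
  k <- ncol(fit$modes)
  if (is.null(mean_threshold)) {
    mean_threshold <- default_mean_threshold(signal$value)
  }
  mean_values <- colMeans(fit$modes)
  baseline_idx <- unname(which(abs(mean_values) > mean_threshold))
  pool <- setdiff(seq_len(k), baseline_idx)
  if (length(pool) == 0) {
    abort("All modes were flagged as baseline drift: nothing left to denoise.")
  }
  ## the drift estimate is removed from the signal before correlating:
  ## otherwise a large wander dominates the signal's variance and dilutes
  ## every oscillatory mode's correlation
  compare <- signal$value
  if (length(baseline_idx) > 0) {
    compare <- compare - rowSums(fit$modes[, baseline_idx, drop = FALSE])
  }
  if (sd(compare) == 0) {
    abort("Signal is constant after baseline removal: selection undefined.")
  }
  rho <- rep(NA_real_, k)
  for (i in pool) {
    rho[i] <- interrelation_number(fit$modes[, i], compare)
  }
  rho_cmp <- if (rho_mode == "absolute") abs(rho) else rho
  mu <- selection_threshold(rho_cmp[pool], fallback = mu_fallback)
  effective_idx <- pool[rho_cmp[pool] >= mu]
  noise_idx <- pool[rho_cmp[pool] < mu]
  if (length(effective_idx) == 0) {
    abort("No mode passed the correlation threshold: nothing left to denoise.")
  }
  structure(
    list(
      baseline_idx = baseline_idx,
      effective_idx = effective_idx,
      noise_idx = noise_idx,
      rho = rho,
      mu = mu,
      mean_values = mean_values,
      mean_threshold = mean_threshold,
      rho_mode = rho_mode,
      center_freqs_hz = center_frequencies_hz(fit)
    ),
    class = "mode_selection"
  )
}

#' @export
print.mode_selection <- function(x, ...) {
  cat(sprintf(
    "<mode_selection> %d baseline, %d effective, %d noise (mu = %.4g, mean threshold = %.4g mV)\n",
    length(x$baseline_idx), length(x$effective_idx), length(x$noise_idx),
    x$mu, x$mean_threshold
  ))
  invisible(x)
}

#' @rdname select_modes
#' @param x,object A `mode_selection` object.
#' @param ... Unused.
#' @export
tidy.mode_selection <- function(x, ...) {
  k <- length(x$mean_values)
  role <- rep("noise", k)
  role[x$effective_idx] <- "effective"
  role[x$baseline_idx] <- "baseline"
  tibble(
    mode = paste0("imf", seq_len(k)),
    center_freq_hz = x$center_freqs_hz,
    mean_mv = unname(x$mean_values),
    rho = x$rho,
    role = factor(role, levels = c("baseline", "effective", "noise"))
  )
}

#' @rdname select_modes
#' @export
glance.mode_selection <- function(x, ...) {
  tibble(
    n_baseline = length(x$baseline_idx),
    n_effective = length(x$effective_idx),
    n_noise = length(x$noise_idx),
    mu = x$mu,
    mean_threshold = x$mean_threshold,
    rho_mode = x$rho_mode
  )
}

#' @rdname select_modes
#' @export
autoplot.mode_selection <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$mode, y = .data$rho, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mu, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(rho),
                  title = "Mode selection (dashed line: threshold mu)")
}
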