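#' Hankel embedding of a sequence
#'
#' Builds the `p x q` Hankel trajectory matrix `H[i, j] = x[i + j - 1]`
#' (constant anti-diagonals), with `p + q - 1 = length(x)`. The default row
#' count `p = floor(n / 2) + 1` gives the near-square shape that maximises
#' the separability of signal and noise subspaces.
#'
#' @param x Numeric vector (length >= 3) or signal tibble.
#' @param p Row count, `2 <= p <= n - 1`.
#' @return A `p x q` numeric matrix.
#' @examples
#' hankel_embed(c(1, 2, 3), p = 2) # rbind(c(1, 2), c(2, 3))
#' @export
hankel_embed <- function(x, p = NULL) {
  x <- pull_values(x)
  n <- length(x)
  if (n < 3) abort("`x` must have at least 3 samples.")
  if (is.null(p)) p <- floor(n / 2) + 1
  if (p < 2 || p > n - 1) abort(sprintf("`p` must lie in [2, %d].", n - 1))
  q <- n - p + 1
  matrix(x[outer(seq_len(p), seq_len(q) - 1L, `+`)], nrow = p, ncol = q)
}

#' Average a matrix back to a sequence along anti-diagonals
#'
#' The adjoint of [hankel_embed()] in the averaging sense: element `k` of
#' the output is the mean of `H[i, j]` over all `i + j - 1 = k`. For an
#' exact Hankel matrix this recovers the generating sequence exactly; for a
#' rank-truncated matrix it is the standard projection back to signal space.
#'
#' @param H Numeric matrix.
#' @return Numeric vector of length `nrow(H) + ncol(H) - 1`.
#' @examples
#' hankel_reconstruct(rbind(c(1, 3), c(3, 5))) # 1 3 5
#' @export
hankel_reconstruct <- function(H) {
  if (!is.matrix(H)) abort("`H` must be a matrix.")
  p <- nrow(H)
  q <- ncol(H)
  idx <- as.vector(outer(seq_len(p), seq_len(q) - 1L, `+`))
  sums <- rowsum(as.vector(H), idx)
  counts <- tabulate(idx, nbins = p + q - 1)
  as.vector(sums) / counts
}

#' Singular value difference spectrum
#'
#' Gaps `d[i] = sigma[i] - sigma[i+1]` of a non-increasing singular value
#' sequence. The largest gap (earliest index on ties) marks the boundary
#' between the signal subspace and the noise floor: `order` is the number
#' of singular values to retain.
#'
#' @param singular_values Non-increasing, non-negative numeric vector,
#'   length >= 2.
#' @return An object of class `diff_spectrum`: list with `singular_values`,
#'   `diffs` and `order`. `tidy()` returns one row per singular value.
#' @examples
#' difference_spectrum(c(10, 9.5, 0.1, 0.09))$order # 2
#' @export
difference_spectrum <- function(singular_values) {
  s <- as.numeric(singular_values)
  if (length(s) < 2) abort("Need at least 2 singular values.")
  if (any(s < -1e-12)) abort("Singular values must be non-negative.")
  if (any(diff(s) > 1e-9 * max(s, 1))) {
    abort("`singular_values` must be non-increasing.")
  }
  d <- -diff(s)
  structure(
    list(singular_values = s, diffs = d, order = which.max(d)),
    class = "diff_spectrum"
  )
}

#' @export
print.diff_spectrum <- function(x, ...) {
  cat(sprintf("<diff_spectrum> %d singular values, selected order %d\n",
              length(x$singular_values), x$order))
  invisible(x)
}

#' @rdname difference_spectrum
#' @param x,object A `diff_spectrum` object.
#' @param ... Unused.
#' @export
tidy.diff_spectrum <- function(x, ...) {
  tibble(
    index = seq_along(x$singular_values),
    sigma = x$singular_values,
    diff = c(x$diffs, NA_real_),
    retained = seq_along(x$singular_values) <= x$order
  )
}

#' @rdname difference_spectrum
#' @export
autoplot.diff_spectrum <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$index, y = .data$sigma,
                                 colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "index", y = expression(sigma[i]),
                  title = "Singular value spectrum")
}

## Core SVD denoising of one block: embed, truncate at the difference
## spectrum order, average back. Returns the input unchanged (with a
## warning) when no noise floor is visible.
svd_denoise_block <- function(x) {
  H <- hankel_embed(x)
  sv <- svd(H)
  ds <- difference_spectrum(sv$d)
  r <- ds$order
  if (r == length(sv$d) - 1) {
    warn("Difference spectrum found no clear noise floor; keeping all components.")
    return(x)
  }
  Hr <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
  hankel_reconstruct(Hr)
}

#' SVD-denoise a sequence via its Hankel matrix
#'
#' Embeds the sequence in a near-square Hankel matrix, zeroes every singular
#' value past the largest gap in the singular value difference spectrum, and
#' averages the rank-truncated matrix back along anti-diagonals. Structured
#' (low-rank Hankel) content passes through; broadband noise, whose energy
#' spreads across the whole spectrum, is suppressed.
#'
#' Sequences longer than `long_threshold` samples are processed in windows
#' of `window` samples with 50% overlap and linear crossfading, bounding
#' the cubic SVD cost; each window gets its own truncation order.
#'
#' @param x Numeric vector (length >= 8) or signal tibble.
#' @param window Window length in samples for long inputs.
#' @param long_threshold Lengths above this are windowed.
#' @return Denoised sequence: a numeric vector (or signal tibble, matching
#'   the input type).
#' @examples
#' t <- seq(0, 1, length.out = 256)
#' clean <- sin(2 * pi * 12 * t)
#' noisy <- clean + rnorm(256, sd = 0.3)
#' snr_db(clean, svd_denoise(noisy)) > snr_db(clean, noisy)
#' @export
svd_denoise <- function(x, window = 2048, long_threshold = 5000) {
  vals <- pull_values(x)
  n <- length(vals)
  if (n < 8) abort("`x` must have at least 8 samples.")
  if (all(vals == 0)) {
    out <- vals
  } else if (n <= long_threshold) {
    out <- svd_denoise_block(vals)
  } else {
    out <- svd_denoise_windowed(vals, window)
  }
  if (is.data.frame(x)) {
    res <- validate_signal(x)
    res$value <- out
    res
  } else {
    out
  }
}

## Overlap-add with 50% overlap and linear crossfade ramps; edge windows
## keep full weight at the record boundaries so weights always sum to 1.
svd_denoise_windowed <- function(x, window) {
  n <- length(x)
  hop <- floor(window / 2)
  starts <- seq(1, n - window + 1, by = hop)
  if (starts[length(starts)] + window - 1 < n) starts <- c(starts, n - window + 1)
  acc <- numeric(n)
  wacc <- numeric(n)
  ramp <- seq(0, 1, length.out = hop)
  for (s in starts) {
    idx <- s:(s + window - 1)
    w <- rep(1, window)
    if (s > 1) w[seq_len(hop)] <- ramp
    if (s + window - 1 < n) w[(window - hop + 1):window] <- rev(ramp)
    acc[idx] <- acc[idx] + w * svd_denoise_block(x[idx])
    wacc[idx] <- wacc[idx] + w
  }
  acc / wacc
}
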