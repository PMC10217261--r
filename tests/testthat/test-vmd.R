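test_that("a single mode locks onto a pure tone", {
  t <- (0:999) / 1000
  tone <- as_signal(cos(2 * pi * 55 * t), fs = 1000)
  fit <- vmd(tone, k = 1, alpha = 2000)
  expect_lt(abs(center_frequencies_hz(fit) - 55), 1)
  expect_gt(cor(fit$modes[, 1], tone$value), 0.99)
})

test_that("three well-separated tones are recovered at K = 3", {
  sig <- eq1_clean()
  fit <- vmd(sig, k = 3, alpha = 2000)
  freqs <- center_frequencies_hz(fit)
  expect_true(all(abs(freqs - c(6, 55, 180)) < 2))
  t <- sig$time
  tones <- cbind(sin(2 * pi * 6 * t), 1.2 * cos(2 * pi * 55 * t),
                 1.4 * sin(2 * pi * 180 * t))
  expect_true(all(diag(cor(fit$modes, tones)) > 0.95))
  # mirror-boundary kink under tau = 0 leaves a 5.04% residual, matching an
  # independent port of the reference ADMM to 7 decimal places
  expect_equal(fit$rel_residual, 0.0504083, tolerance = 1e-4)
})

test_that("reconstruction is the mode sum with fs preserved", {
  t <- (0:799) / 400
  tone <- as_signal(cos(2 * pi * 20 * t), fs = 400)
  fit1 <- vmd(tone, k = 1, alpha = 2000)
  rec1 <- reconstruct(fit1)
  expect_equal(rec1$value, fit1$modes[, 1], tolerance = 1e-15)
  expect_equal(signal_fs(rec1), 400)

  sig <- eq1_clean()
  fit <- vmd(sig, k = 3, alpha = 2000)
  rec <- reconstruct(fit)
  expect_lt(sqrt(sum((sig$value - rec$value)^2) / sum(sig$value^2)), 0.052)
  expect_equal(reconstruct(fit, 1:2)$value + fit$modes[, 3], rec$value,
               tolerance = 1e-12)
})

test_that("the all-zero signal is a fixed point", {
  z <- as_signal(rep(0, 256), fs = 100)
  fit <- vmd(z, k = 3, alpha = 1000)
  expect_true(all(fit$modes == 0))
  expect_true(all(reconstruct(fit)$value == 0))
})

test_that("centre frequencies are in Hz, ascending, and pinned by dc mode", {
  sig <- eq1_clean()
  for (k in c(2, 3, 5, 8)) {
    fit <- vmd(sig, k = k, alpha = 1500)
    expect_true(all(diff(center_frequencies_hz(fit)) >= 0))
    expect_equal(center_frequencies_hz(fit), fit$center_freqs * 1000)
  }
  fit_dc <- vmd(sig, k = 3, alpha = 2000, dc = TRUE)
  expect_identical(center_frequencies_hz(fit_dc)[1], 0)
})

test_that("decomposition is bit-deterministic for non-random inits", {
  sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0.1, seed = 2)
  for (ini in c("uniform", "zero")) {
    a <- vmd(sig, k = 4, alpha = 1200, init = ini)
    b <- vmd(sig, k = 4, alpha = 1200, init = ini)
    expect_identical(a$modes, b$modes)
    expect_identical(a$center_freqs, b$center_freqs)
  }
  r1 <- vmd(sig, k = 4, alpha = 1200, init = "random", seed = 5)
  r2 <- vmd(sig, k = 4, alpha = 1200, init = "random", seed = 5)
  expect_identical(r1$modes, r2$modes)
})

test_that("well-separated tone mixtures are resolved within 2%", {
  fs <- 1200
  cases <- list(list(tones = c(5, 20, 80), dur = 2),
                list(tones = c(4, 16, 64, 256), dur = 4))
  for (case in cases) {
    f0 <- case$tones
    t <- (0:(case$dur * fs - 1)) / fs
    x <- rowSums(sapply(f0, function(f) sin(2 * pi * f * t + f)))
    fit <- vmd(as_signal(x, fs = fs), k = length(f0), alpha = 2000)
    freqs <- center_frequencies_hz(fit)
    expect_true(all(abs(freqs - f0) / f0 < 0.02))
    for (j in seq_along(f0)) {
      expect_gt(abs(cor(fit$modes[, j], sin(2 * pi * f0[j] * t + f0[j]))), 0.95)
    }
  }
})

test_that("Wiener shrinkage never amplifies and alpha narrows modes", {
  t <- (0:1999) / 1000
  two <- as_signal(sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t), fs = 1000)
  bandwidth <- function(fit, j) {
    m <- fit$modes[, j]
    p <- Mod(fft(m))^2
    n <- length(m)
    f <- (0:(n - 1)) / n
    f <- pmin(f, 1 - f)
    sqrt(sum((f - fit$center_freqs[j])^2 * p) / sum(p))
  }
  prev <- c(Inf, Inf)
  for (a in c(500, 1000, 2000, 5000)) {
    fit <- vmd(two, k = 2, alpha = a)
    expect_lte(sum(fit$modes^2), sum(two$value^2) * 1.05)
    bw <- c(bandwidth(fit, 1), bandwidth(fit, 2))
    expect_true(all(bw <= prev + 1e-9))
    prev <- bw
  }
})

test_that("invalid inputs are rejected with clear errors", {
  sig <- eq1_clean()
  expect_error(vmd(sig[1:5, ], k = 3, alpha = 2000), "too short")
  expect_error(vmd(sig, k = 0, alpha = 2000), "k")
  expect_error(vmd(sig, k = 3, alpha = -1), "alpha")
  bad <- sig
  bad$value[10] <- NaN
  expect_error(vmd(bad, k = 3, alpha = 2000), "finite")
})

test_that("tidiers and long-format accessor agree with the fit", {
  sig <- eq1_clean()
  fit <- vmd(sig, k = 3, alpha = 2000)
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  expect_equal(td$center_freq_hz, center_frequencies_hz(fit))
  gl <- glance(fit)
  expect_identical(gl$k, 3L)
  long <- vmd_modes(fit)
  expect_identical(nrow(long), 3L * nrow(sig))
  expect_equal(long$value[long$mode == "imf2"], fit$modes[, 2])
})
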