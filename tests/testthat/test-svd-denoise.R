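test_that("Hankel embedding has constant anti-diagonals and round-trips", {
  expect_identical(hankel_embed(c(1, 2, 3), p = 2), rbind(c(1, 2), c(2, 3)))
  set.seed(4)
  for (n in c(9L, 16L, 101L)) {
    x <- rnorm(n)
    H <- hankel_embed(x)
    idx <- row(H) + col(H) - 1
    for (k in unique(as.vector(idx))) {
      vals <- H[idx == k]
      expect_true(all(vals == vals[1]))
    }
    expect_equal(hankel_reconstruct(H), x, tolerance = 1e-15)
    expect_identical(dim(H)[1] + dim(H)[2] - 1L, n)
  }
  expect_error(hankel_embed(rnorm(10), p = 10), "\\[2, 9\\]")
})

test_that("anti-diagonal averaging matches the definition", {
  expect_equal(hankel_reconstruct(rbind(c(1, 3), c(3, 5))), c(1, 3, 5))
  H <- rbind(c(1, 2), c(10, 20))  # not Hankel: average the anti-diagonal
  expect_equal(hankel_reconstruct(H), c(1, (2 + 10) / 2, 20))
})

test_that("difference spectrum finds the largest gap (earliest on ties)", {
  ds <- difference_spectrum(c(10, 9.5, 0.1, 0.09))
  expect_equal(ds$diffs, c(0.5, 9.4, 0.01))
  expect_identical(ds$order, 2L)
  expect_identical(difference_spectrum(c(5, 3, 1))$order, 1L)  # tie -> earliest
  expect_error(difference_spectrum(7), "at least 2")
  expect_error(difference_spectrum(c(1, 2)), "non-increasing")
})

test_that("difference spectrum recovers the true Hankel rank", {
  t <- (0:1799) / 360
  svals <- function(x) svd(hankel_embed(x), nu = 0, nv = 0)$d
  expect_identical(difference_spectrum(svals(sin(2 * pi * 7 * t)))$order, 2L)
  two <- sin(2 * pi * 7 * t) + 0.8 * sin(2 * pi * 19.37 * t)
  expect_identical(difference_spectrum(svals(two))$order, 4L)
  # r in {1, 2, 4, 6}: exponential (rank 1) and 1-3 incommensurate tones
  expect_identical(difference_spectrum(svals(exp(-t / 3)))$order, 1L)
  three <- two + 0.6 * sin(2 * pi * 47.3 * t)
  expect_identical(difference_spectrum(svals(three))$order, 6L)
})

test_that("a noiseless sinusoid passes through SVD denoising unchanged", {
  t <- (0:599) / 360
  x <- sin(2 * pi * 9 * t)
  y <- svd_denoise(x)
  expect_lt(sqrt(sum((x - y)^2) / sum(x^2)), 1e-6)
  expect_identical(svd_denoise(rep(0, 64)), rep(0, 64))
  expect_error(svd_denoise(rnorm(5)), "at least 8")
})

test_that("denoising a 10 dB noisy sinusoid gains at least 5 dB", {
  t <- (0:1799) / 360
  clean <- sin(2 * pi * 7 * t)
  gains <- vapply(1:20, function(s) {
    noisy <- add_noise_at_snr(as_signal(clean, fs = 360), 10, seed = s)
    snr_db(clean, svd_denoise(noisy$value)) - snr_db(clean, noisy$value)
  }, numeric(1))
  expect_gte(median(gains), 5)
})

test_that("denoising gains hold across noise levels", {
  t <- (0:1799) / 360
  clean <- sin(2 * pi * 7 * t)
  for (level in c(5, 10, 20)) {
    gains <- vapply(1:10, function(s) {
      noisy <- add_noise_at_snr(as_signal(clean, fs = 360), level, seed = 100 + s)
      snr_db(clean, svd_denoise(noisy$value)) - level
    }, numeric(1))
    expect_gt(median(gains), 0)
  }
})

test_that("truncation plus averaging never adds energy", {
  set.seed(11)
  for (i in 1:6) {
    x <- as.vector(arima.sim(list(ar = 0.9), 200)) + rnorm(200, sd = 0.2)
    y <- suppressWarnings(svd_denoise(x))
    expect_lte(sum(y^2), sum(x^2) + 1e-9)
  }
})

test_that("long inputs are windowed with seamless crossfades", {
  t <- (0:5999) / 360
  clean <- sin(2 * pi * 7 * t)
  noisy <- add_noise_at_snr(as_signal(clean, fs = 360), 10, seed = 2)$value
  y <- svd_denoise(noisy, window = 1024, long_threshold = 2000)
  expect_identical(length(y), length(noisy))
  expect_gt(snr_db(clean, y) - 10, 5)
  # windowed and whole-signal results agree closely away from any boundary
  y_full <- svd_denoise(noisy)
  expect_gt(cor(y, y_full), 0.99)
})

test_that("signal tibbles pass through with their time axis intact", {
  t <- (0:599) / 360
  sig <- as_signal(sin(2 * pi * 9 * t) + rnorm(600, sd = 0.1), fs = 360)
  out <- svd_denoise(sig)
  expect_s3_class(out, "tbl_df")
  expect_identical(out$time, sig$time)
})
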