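test_that("interrelation number is the product-moment correlation", {
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(200)
    y <- rnorm(200) + 0.5 * x
    expect_equal(interrelation_number(x, y), cor(x, y), tolerance = 1e-12)
  }
  x <- rnorm(50)
  expect_equal(interrelation_number(x, x), 1, tolerance = 1e-12)
  expect_equal(interrelation_number(x, -x), -1, tolerance = 1e-12)
})

test_that("orthogonal sinusoids have near-zero interrelation", {
  t <- (0:999) / 1000  # integer periods of both tones
  expect_lt(abs(interrelation_number(sin(2 * pi * 6 * t), sin(2 * pi * 55 * t))),
            0.01)
})

test_that("degenerate interrelation inputs are rejected", {
  expect_error(interrelation_number(rep(1, 10), rnorm(10)), "variance")
  expect_error(interrelation_number(1:5, 1:6), "equal length")
})

test_that("the adaptive threshold follows its closed form", {
  expect_equal(selection_threshold(c(0.2, 0.9, 0.4)), 0.15, tolerance = 1e-12)
  expect_equal(selection_threshold(1), 1 / 7, tolerance = 1e-12)
  expect_error(selection_threshold(0.3), "undefined")
  expect_error(selection_threshold(c(0.1, 0.25)), "undefined")
  expect_identical(selection_threshold(0.25, fallback = 0.1), 0.1)
})

test_that("the threshold strictly decreases in max(rho) above the singularity", {
  m <- seq(0.301, 1, by = 0.001)
  mu <- vapply(m, selection_threshold, numeric(1))
  expect_true(all(diff(mu) < 0))
})

test_that("mean-value criterion flags drift-carrying modes only", {
  t <- (0:1999) / 400
  sig <- as_signal(0.5 + sin(2 * pi * 10 * t), fs = 400)
  fit <- vmd(sig, k = 2, alpha = 2000)
  expect_identical(flag_baseline_modes(fit, mean_threshold = 0.05), 1L)
  zm <- as_signal(sin(2 * pi * 10 * t), fs = 400)
  fitz <- vmd(zm, k = 1, alpha = 2000)
  for (thr in c(1e-6, 1e-3, 0.05, 1)) {
    expect_length(flag_baseline_modes(fitz, mean_threshold = thr), 0)
  }
})

test_that("flagged modes reconstruct the injected drift", {
  pair <- benchmark_pair(1)
  fit <- vmd(pair$noisy, k = 11, alpha = 3194)
  idx <- flag_baseline_modes(fit)
  expect_gt(length(idx), 0)
  drift_hat <- rowSums(fit$modes[, idx, drop = FALSE])
  expect_gt(cor(drift_hat, benchmark_drift()$value), 0.8)
})

test_that("a single clean mode is always effective", {
  t <- (0:999) / 1000
  tone <- as_signal(cos(2 * pi * 30 * t), fs = 1000)
  fit <- vmd(tone, k = 1, alpha = 2000)
  sel <- select_modes(fit)
  expect_identical(sel$effective_idx, 1L)
  expect_length(sel$baseline_idx, 0)
  expect_gte(max(sel$rho, na.rm = TRUE), sel$mu)
})

test_that("a constructed drift/signal/noise mixture partitions correctly", {
  pair <- benchmark_pair(2)
  fit <- vmd(pair$noisy, k = 11, alpha = 3194)
  sel <- select_modes(fit, mu_fallback = 0.1)
  td <- tidy(sel)
  # drift mode: lowest frequency, large mean
  expect_true(1L %in% sel$baseline_idx)
  # ECG-band modes effective, high-frequency noise modes rejected
  expect_true(all(td$role[td$center_freq_hz > 1 & td$center_freq_hz < 15] == "effective"))
  expect_true(all(td$role[td$center_freq_hz > 45] == "noise"))
})

test_that("the partition is disjoint and exhaustive on every run", {
  for (s in 1:4) {
    sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0.2, seed = s)
    k <- 2L + s
    sel <- select_modes(vmd(sig, k = k, alpha = 1500), mu_fallback = 0.1)
    all_idx <- sort(c(sel$baseline_idx, sel$effective_idx, sel$noise_idx))
    expect_identical(as.integer(all_idx), seq_len(k))
    expect_identical(
      length(sel$baseline_idx) + length(sel$effective_idx) + length(sel$noise_idx),
      k
    )
    # threshold semantics: effective >= mu, noise < mu
    expect_true(all(sel$rho[sel$effective_idx] >= sel$mu))
    expect_true(all(sel$rho[sel$noise_idx] < sel$mu))
  }
})

test_that("selection fails loudly when nothing remains", {
  t <- (0:999) / 1000
  tone <- as_signal(cos(2 * pi * 30 * t), fs = 1000)
  fit <- vmd(tone, k = 1, alpha = 2000)
  # negative threshold flags every mode as baseline
  expect_error(select_modes(fit, mean_threshold = -1), "baseline")
})
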