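test_that("envelope entropy is maximal for a flat envelope and low for bursts", {
  n <- 512
  t <- (0:(n - 1)) / n
  tone <- sin(2 * pi * 8 * t)  # integer periods: exactly constant envelope
  expect_equal(envelope_entropy(tone), log(n), tolerance = 1e-9)
  am <- (1 + 0.8 * sin(2 * pi * 2 * t)) * sin(2 * pi * 64 * t)
  expect_lt(envelope_entropy(am), envelope_entropy(tone))
  impulse <- c(1, rep(0, n - 1))
  expect_lt(envelope_entropy(impulse), 0.8 * log(n))
  expect_error(envelope_entropy(rep(0, 16)), "all zero")
  expect_error(envelope_entropy(c(1, 2)), "at least 4")
})

test_that("vmd fitness reduces to the single-mode entropy at K = 1", {
  t <- (0:999) / 1000
  tone <- as_signal(cos(2 * pi * 40 * t), fs = 1000)
  fit <- vmd(tone, k = 1, alpha = 2000)
  expect_equal(vmd_fitness(tone, k = 1, alpha = 2000),
               envelope_entropy(fit$modes[, 1]), tolerance = 1e-12)
})

test_that("vmd fitness is finite over the parameter box and noise raises it", {
  sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0.1, seed = 7)
  for (k in c(2, 6, 10, 15)) {
    for (a in c(500, 2000, 5000)) {
      f <- vmd_fitness(sig, k = k, alpha = a)
      expect_true(is.finite(f) && f > 0)
    }
  }
  t <- (0:999) / 1000
  clean <- as_signal(cos(2 * pi * 50 * t), fs = 1000)
  noisy <- add_noise_at_snr(clean, 10, seed = 3)
  expect_lte(vmd_fitness(clean, k = 2, alpha = 2000),
             vmd_fitness(noisy, k = 2, alpha = 2000))
})

test_that("sparrow search solves standard test problems", {
  sphere <- ssa_optimize(function(x) sum(x^2), c(-5, -5), c(5, 5),
                         pop_size = 30, max_iter = 100, seed = 1)
  expect_lt(sphere$best_fitness, 1e-3)
  quad <- ssa_optimize(function(x) (x - 3)^2, 0, 10,
                       pop_size = 30, max_iter = 100, seed = 2)
  expect_lt(abs(quad$best_position - 3), 0.05)
})

test_that("the recorded global best is monotone and consistent", {
  rast <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  for (s in 1:5) {
    res <- ssa_optimize(rast, c(-5.12, -5.12), c(5.12, 5.12),
                        pop_size = 20, max_iter = 40, seed = s)
    expect_true(all(diff(res$convergence) <= 0))
    expect_identical(res$best_fitness, res$convergence[length(res$convergence)])
    expect_identical(length(res$convergence), 40L)
    expect_true(all(res$best_position >= -5.12 & res$best_position <= 5.12))
  }
})

test_that("a constant objective converges immediately", {
  res <- ssa_optimize(function(x) 7.5, c(0, 0), c(1, 1),
                      pop_size = 10, max_iter = 5, seed = 1)
  expect_identical(res$best_fitness, 7.5)
  expect_true(all(res$convergence == 7.5))
})

test_that("integer dimensions stay integer and bounds hold at every evaluation", {
  seen_bad <- FALSE
  fn <- function(x) {
    if (x[1] != round(x[1]) || x[1] < 2 || x[1] > 15 ||
        x[2] < 500 || x[2] > 5000) seen_bad <<- TRUE
    (x[1] - 7)^2 + (x[2] - 2000)^2 / 1e4
  }
  res <- ssa_optimize(fn, c(2, 500), c(15, 5000), pop_size = 15, max_iter = 20,
                      integer_dims = 1, seed = 4)
  expect_false(seen_bad)
  expect_identical(res$best_position[1], round(res$best_position[1]))
})

test_that("search is reproducible and rejects non-finite objectives", {
  f <- function(x) sum(abs(x))
  a <- ssa_optimize(f, c(-2, -2), c(2, 2), pop_size = 12, max_iter = 15, seed = 9)
  b <- ssa_optimize(f, c(-2, -2), c(2, 2), pop_size = 12, max_iter = 15, seed = 9)
  expect_identical(a$best_position, b$best_position)
  expect_identical(a$convergence, b$convergence)
  expect_error(
    ssa_optimize(function(x) NaN, c(0, 0), c(1, 1), pop_size = 5, max_iter = 2,
                 seed = 1),
    "non-finite"
  )
})

test_that("parameter tuning stays in its box and matches brute force", {
  sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0.1, seed = 7)
  grid <- expand.grid(k = 2:15, a = seq(500, 5000, by = 500))
  grid_best <- min(mapply(function(k, a) vmd_fitness(sig, k, a), grid$k, grid$a))
  tuned <- tune_vmd(sig, seed = 3)
  expect_true(tuned$k >= 2 && tuned$k <= 15)
  expect_true(tuned$alpha >= 500 && tuned$alpha <= 5000)
  expect_lte(tuned$fitness, grid_best + 0.05)
  expect_identical(length(tuned$ssa$convergence), 15L)
  expect_true(all(diff(tuned$ssa$convergence) <= 0))
})
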