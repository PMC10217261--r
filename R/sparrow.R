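#' Sparrow search optimisation
#'
#' Minimises an objective over a bounded box with the sparrow search
#' algorithm (SSA), a population metaheuristic with three behavioural roles
#' re-assigned by fitness rank at every iteration:
#'
#' * *producers* (the best fraction) explore: while the alarm value stays
#'   below `safety` they contract exponentially, otherwise they take a
#'   Gaussian step;
#' * *scroungers* (the rest) follow: the worse half relocates away from the
#'   worst individual, the better half jumps around the best producer;
#' * *scouts* (a random fraction) guard against stagnation by relocating
#'   relative to the global best / worst.
#'
#' Positions are clamped to the bounds and integer dimensions are rounded
#' after every move, so the objective is only ever evaluated at feasible
#' points. The recorded global best is monotone non-increasing, ties keep
#' the earlier-found position, and the whole run is reproducible from
#' `seed`.
#'
#' @param fn Objective: takes a numeric position vector, returns a finite
#'   scalar. A non-finite value aborts with the offending position.
#' @param lower,upper Numeric vectors of box bounds (equal length).
#' @param pop_size Population size (>= 2).
#' @param max_iter Number of iterations (>= 1).
#' @param producer_frac Fraction of the population acting as producers.
#' @param scout_frac Fraction re-assigned as scouts each iteration.
#' @param safety Alarm threshold in (0, 1) switching the producer move.
#' @param integer_dims Integer indices of dimensions constrained to integers.
#' @param seed Optional integer seed.
#'
#' @return An object of class `ssa_result` with `best_position`,
#'   `best_fitness`, `convergence` (per-iteration global best, length
#'   `max_iter`, non-increasing) and `evaluations`. `tidy()` returns the
#'   convergence curve as a tibble; `glance()` a one-row summary.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ssa_optimize(sphere, lower = c(-5, -5), upper = c(5, 5),
#'                     pop_size = 30, max_iter = 50, seed = 1)
#' res$best_fitness
#' @export
ssa_optimize <- function(fn, lower, upper, pop_size = 30, max_iter = 15,
                         producer_frac = 0.2, scout_frac = 0.1, safety = 0.8,
                         integer_dims = NULL, seed = NULL) {
  d <- length(lower)
  if (length(upper) != d) abort("`lower` and `upper` must have equal length.")
  if (any(lower >= upper)) abort("Each lower bound must be below its upper bound.")
  if (pop_size < 2) abort("`pop_size` must be >= 2.")
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  if (safety <= 0 || safety >= 1) abort("`safety` must lie in (0, 1).")

  feasible <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    if (!is.null(integer_dims)) x[integer_dims] <- round(x[integer_dims])
    x
  }
  n_eval <- 0L
  evaluate <- function(x) {
    f <- fn(x)
    n_eval <<- n_eval + 1L
    if (!is.finite(f)) {
      abort(sprintf("Objective returned a non-finite value at (%s).",
                    paste(signif(x, 6), collapse = ", ")))
    }
    f
  }

  run <- function() {
    X <- matrix(0, pop_size, d)
    for (i in seq_len(pop_size)) {
      X[i, ] <- feasible(lower + runif(d) * (upper - lower))
    }
    f <- apply(X, 1, evaluate)
    best_i <- which.min(f)
    gbest_x <- X[best_i, ]
    gbest_f <- f[best_i]

    n_prod <- max(1L, round(producer_frac * pop_size))
    n_scout <- max(1L, round(scout_frac * pop_size))
    convergence <- numeric(max_iter)

    for (it in seq_len(max_iter)) {
      ord <- order(f)
      X <- X[ord, , drop = FALSE]
      f <- f[ord]
      worst_x <- X[pop_size, ]
      worst_f <- f[pop_size]

      alarm <- runif(1)
      for (i in seq_len(n_prod)) {
        X[i, ] <- feasible(if (alarm < safety) {
          X[i, ] * exp(-i / (runif(1) * max_iter))
        } else {
          X[i, ] + rnorm(1)
        })
      }
      prod_best <- X[1, ]
      for (i in seq.int(n_prod + 1, pop_size)) {
        X[i, ] <- feasible(if (i > pop_size / 2) {
          rnorm(1) * exp((worst_x - X[i, ]) / i^2)
        } else {
          dir <- sample(c(-1, 1), d, replace = TRUE)
          prod_best + mean(abs(X[i, ] - prod_best) * dir)
        })
      }
      f <- apply(X, 1, evaluate)
      if (min(f) < gbest_f) {
        gbest_f <- min(f)
        gbest_x <- X[which.min(f), ]
      }

      scouts <- sample(pop_size, n_scout)
      for (i in scouts) {
        if (f[i] > gbest_f) {
          X[i, ] <- feasible(gbest_x + rnorm(d) * abs(X[i, ] - gbest_x))
        } else {
          step <- runif(1, -1, 1)
          X[i, ] <- feasible(X[i, ] + step * abs(X[i, ] - worst_x) /
                               (f[i] - worst_f + .Machine$double.eps))
        }
        f[i] <- evaluate(X[i, ])
      }
      if (min(f) < gbest_f) {
        gbest_f <- min(f)
        gbest_x <- X[which.min(f), ]
      }
      convergence[it] <- gbest_f
    }
    list(x = gbest_x, f = gbest_f, convergence = convergence)
  }

  out <- with_seed_or_local(seed, run())
  structure(
    list(
      best_position = out$x,
      best_fitness = out$f,
      convergence = out$convergence,
      evaluations = n_eval,
      config = list(pop_size = pop_size, max_iter = max_iter,
                    producer_frac = producer_frac, scout_frac = scout_frac,
                    safety = safety, lower = lower, upper = upper,
                    integer_dims = integer_dims, seed = seed)
    ),
    class = "ssa_result"
  )
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf(
    "<ssa_result> best fitness %.6g at (%s) after %d evaluations\n",
    x$best_fitness, paste(signif(x$best_position, 6), collapse = ", "),
    x$evaluations
  ))
  invisible(x)
}

#' @rdname ssa_optimize
#' @param x,object An `ssa_result` object.
#' @param ... Unused.
#' @export
tidy.ssa_result <- function(x, ...) {
  tibble(iteration = seq_along(x$convergence), best_fitness = x$convergence)
}

#' @rdname ssa_optimize
#' @export
glance.ssa_result <- function(x, ...) {
  tibble(
    best_fitness = x$best_fitness,
    evaluations = x$evaluations,
    iterations = length(x$convergence),
    pop_size = x$config$pop_size
  )
}

#' @rdname ssa_optimize
#' @export
autoplot.ssa_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = "Sparrow search convergence")
}

#' Select VMD parameters by sparrow search
#'
#' Runs [ssa_optimize()] over the integer box `k_range` x `alpha_range`
#' with the envelope-entropy fitness of [vmd_fitness()], i.e. it searches
#' for the `(k, alpha)` whose decomposition contains the most structured
#' (lowest envelope entropy) mode. Defaults follow the usual ECG protocol:
#' `k` in \[2, 15\], `alpha` in \[500, 5000\], population 30, 15 iterations.
#'
#' Fitness values are memoised on the integer `(k, alpha)` lattice, so
#' revisited positions cost nothing; this changes no result, only run time.
#'
#' @inheritParams vmd_fitness
#' @param k_range,alpha_range Integer search intervals `c(low, high)`.
#' @param pop_size,iterations Sparrow search budget.
#' @param seed Optional integer seed controlling the whole search.
#' @param ... Passed to [vmd_fitness()] (and on to [vmd()]).
#'
#' @return An object of class `vmd_tuning`: list with `k`, `alpha`,
#'   `fitness` and the full `ssa` result. `tidy()`/`glance()`/`autoplot()`
#'   delegate to the embedded `ssa_result`.
#' @examples
#' \donttest{
#' sig <- gen_test_signal(fs = 1000, duration = 1, noise_sd = 0.1, seed = 1)
#' tuned <- tune_vmd(sig, pop_size = 10, iterations = 5, seed = 1)
#' }
#' @export
tune_vmd <- function(signal, k_range = c(2L, 15L), alpha_range = c(500L, 5000L),
                     pop_size = 30, iterations = 15, aggregate = c("min", "mean"),
                     seed = NULL, ...) {
  signal <- validate_signal(signal)
  aggregate <- match.arg(aggregate)
  if (nrow(signal) < 2 * k_range[2]) {
    abort("Signal too short for the upper end of `k_range`.")
  }
  cache <- new.env(parent = emptyenv())
  objective <- function(pos) {
    key <- paste0(pos[1], ":", pos[2])
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- vmd_fitness(signal, k = pos[1], alpha = pos[2],
                       aggregate = aggregate, ...)
    assign(key, val, envir = cache)
    val
  }
  res <- ssa_optimize(objective,
                      lower = c(k_range[1], alpha_range[1]),
                      upper = c(k_range[2], alpha_range[2]),
                      pop_size = pop_size, max_iter = iterations,
                      integer_dims = 1:2, seed = seed)
  structure(
    list(
      k = as.integer(round(res$best_position[1])),
      alpha = as.integer(round(res$best_position[2])),
      fitness = res$best_fitness,
      ssa = res
    ),
    class = "vmd_tuning"
  )
}

#' @export
print.vmd_tuning <- function(x, ...) {
  cat(sprintf("<vmd_tuning> k = %d, alpha = %d (envelope entropy %.5g)\n",
              x$k, x$alpha, x$fitness))
  invisible(x)
}

#' @rdname tune_vmd
#' @param x,object A `vmd_tuning` object.
#' @export
tidy.vmd_tuning <- function(x, ...) tidy(x$ssa)

#' @rdname tune_vmd
#' @export
glance.vmd_tuning <- function(x, ...) {
  dplyr::bind_cols(tibble(k = x$k, alpha = x$alpha), glance(x$ssa))
}

#' @rdname tune_vmd
#' @export
autoplot.vmd_tuning <- function(object, ...) autoplot(object$ssa)
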