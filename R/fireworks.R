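#' Fireworks-algorithm configuration
#'
#' Parameters of the fireworks optimizer. The defaults are the canonical
#' values for the algorithm: `n = 5` fireworks, a total explosion-spark
#' budget of `sparks = 50` per generation, amplitude cap `amplitude = 40`
#' gray levels, spark-count bounding constants `a = 0.04` and `b = 0.8`,
#' `gaussian_sparks = 5` mutation sparks, and `iterations = 50`
#' generations (ample for a one-dimensional 255-point threshold search).
#'
#' @param n Number of fireworks per generation (`>= 2`).
#' @param sparks Total explosion-spark budget per generation (`>= n`).
#' @param amplitude Explosion amplitude cap, in the objective's units
#'   (gray levels for thresholding).
#' @param a,b Spark-count bounding fractions, `0 < a < b < 1`: each
#'   firework's spark count is clamped to
#'   `[max(1, round(a * sparks)), round(b * sparks)]`.
#' @param gaussian_sparks Number of Gaussian-mutation sparks per
#'   generation.
#' @param iterations Number of generations (`>= 1`).
#' @param seed Integer random seed; the whole run is reproducible for a
#'   fixed seed. `NULL` leaves the current RNG state untouched.
#' @param lo,hi Search bounds, `lo < hi`; positions are kept in
#'   `[lo, hi)` by modular boundary mapping.
#' @param min_amplitude Floor applied to the per-firework explosion
#'   amplitude when sparks are generated. Thresholding objectives are
#'   evaluated at rounded positions, so an amplitude below one gray
#'   level cannot reach a new candidate; the default floor of 1 keeps
#'   the best firework's sparks able to probe its neighbouring levels.
#'   Set to 0 for a fully continuous objective.
#' @return An `fa_config` list.
#' @export
fa_config <- function(n = 5L, sparks = 50L, amplitude = 40, a = 0.04,
                      b = 0.8, gaussian_sparks = 5L, iterations = 50L,
                      seed = NULL, lo = 0, hi = 254, min_amplitude = 1) {
  cfg <- list(n = as.integer(n), sparks = as.integer(sparks),
              amplitude = as.numeric(amplitude), a = as.numeric(a),
              b = as.numeric(b), gaussian_sparks = as.integer(gaussian_sparks),
              iterations = as.integer(iterations),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              lo = as.numeric(lo), hi = as.numeric(hi),
              min_amplitude = as.numeric(min_amplitude))
  validate_fa_config(cfg)
  structure(cfg, class = "fa_config")
}

validate_fa_config <- function(cfg) {
  if (cfg$n < 2L) stop("fa_config: `n` must be >= 2")
  if (cfg$sparks < cfg$n) stop("fa_config: `sparks` must be >= `n`")
  if (cfg$iterations < 1L) stop("fa_config: `iterations` must be >= 1")
  if (!(cfg$a > 0 && cfg$a < cfg$b && cfg$b < 1))
    stop("fa_config: need 0 < a < b < 1")
  if (cfg$amplitude < 0) stop("fa_config: `amplitude` must be >= 0")
  if (cfg$gaussian_sparks < 0)
    stop("fa_config: `gaussian_sparks` must be >= 0")
  if (cfg$min_amplitude < 0)
    stop("fa_config: `min_amplitude` must be >= 0")
  if (!(cfg$lo < cfg$hi)) stop("fa_config: need `lo` < `hi`")
  invisible(cfg)
}

#' @export
print.fa_config <- function(x, ...) {
  cat(sprintf(paste0("<fa_config> n = %d, sparks = %d, A = %g, a = %g, ",
                     "b = %g, gaussian = %d, iterations = %d, ",
                     "bounds [%g, %g)\n"),
              x$n, x$sparks, x$amplitude, x$a, x$b, x$gaussian_sparks,
              x$iterations, x$lo, x$hi))
  invisible(x)
}

ALLOC_EPS <- 1e-12

#' Explosion spark counts per firework
#'
#' Allocates the generation's spark budget in proportion to fitness
#' (maximization form): raw counts are
#' `sparks * (f_i - f_min + eps) / sum_j (f_j - f_min + eps)`, rounded,
#' then clamped to `[max(1, round(a * sparks)), round(b * sparks)]`.
#' Better fireworks never receive fewer sparks than worse ones, and every
#' firework emits at least one spark.
#'
#' @param fitnesses Fitness of each firework (at least one finite value;
#'   `-Inf` entries are treated as the worst finite fitness).
#' @param config An [fa_config].
#' @return Integer spark counts, one per firework.
#' @export
compute_spark_counts <- function(fitnesses, config) {
  f <- sanitize_fitness(fitnesses)
  m <- config$sparks
  shifted <- f - min(f) + ALLOC_EPS
  raw <- round(m * shifted / sum(shifted))
  lo <- max(1, round(config$a * m))
  hi <- round(config$b * m)
  as.integer(pmin(pmax(raw, lo), hi))
}

#' Explosion amplitudes per firework
#'
#' Allocates explosion ranges inversely to fitness (maximization form):
#' `A_i = amplitude * (f_max - f_i + eps) / sum_j (f_max - f_j + eps)`.
#' The best firework explodes most locally (exploitation), the worst most
#' widely (exploration). All amplitudes lie in `[0, amplitude]`.
#'
#' @inheritParams compute_spark_counts
#' @return Numeric amplitudes, one per firework.
#' @export
compute_amplitudes <- function(fitnesses, config) {
  f <- sanitize_fitness(fitnesses)
  d <- max(f) - f + ALLOC_EPS
  config$amplitude * d / sum(d)
}

sanitize_fitness <- function(fitnesses) {
  if (length(fitnesses) == 0L) stop("at least one fitness value is required")
  fin <- is.finite(fitnesses)
  if (!any(fin)) stop("at least one finite fitness value is required")
  f <- as.numeric(fitnesses)
  f[!fin] <- min(f[fin])
  f
}

#' Modular boundary mapping
#'
#' Positions outside the search interval are mapped back with the
#' canonical modular rule `lo + |position| mod (hi - lo)`; in-bounds
#' positions are returned unchanged. The result always lies in
#' `[lo, hi)`. Vectorized.
#'
#' @param position Numeric position(s).
#' @param lo,hi Bounds with `lo < hi`.
#' @export
map_to_bounds <- function(position, lo, hi) {
  if (!(lo < hi)) stop("need `lo` < `hi`")
  out <- position
  oob <- position < lo | position >= hi
  out[oob] <- lo + abs(position[oob]) %% (hi - lo)
  out
}

#' Explosion sparks around a firework
#'
#' Draws `count` sparks at `position + U(-amplitude, +amplitude)` and
#' maps each back into the search bounds. Uses the current RNG stream,
#' so results are deterministic under a fixed seed.
#'
#' @param position Parent firework position.
#' @param count Number of sparks (`>= 1`).
#' @param amplitude Explosion range (`>= 0`).
#' @param lo,hi Search bounds.
#' @return Numeric vector of `count` mapped spark positions.
#' @export
explode <- function(position, count, amplitude, lo, hi) {
  if (count < 1L) stop("`count` must be >= 1")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  map_to_bounds(position + stats::runif(count, -amplitude, amplitude), lo, hi)
}

#' Gaussian mutation spark
#'
#' Multiplies a position by a draw `g ~ Normal(1, 1)` and maps the result
#' into bounds. The origin is a fixed point of the multiplicative rule.
#'
#' @inheritParams explode
#' @export
gaussian_mutate <- function(position, lo, hi) {
  map_to_bounds(position * stats::rnorm(1, mean = 1, sd = 1), lo, hi)
}

#' Select the next generation of fireworks
#'
#' Keeps the best candidate deterministically (elitism) and fills the
#' remaining `n - 1` slots by sampling without replacement with
#' probability proportional to each candidate's summed distance to all
#' other candidates (crowding favours diverse survivors). If all
#' candidates coincide the distances degenerate and selection falls back
#' to a uniform choice. With fewer than `n` candidates the whole set is
#' kept and padped with uniform random positions (fitness `NA`, to be
#' evaluated by the caller).
#'
#' @param positions,fitnesses Candidate pool.
#' @param n Number of survivors.
#' @param lo,hi Bounds for random padding.
#' @return List with `positions` and `fitnesses` of the `n` survivors.
#' @export
select_next_generation <- function(positions, fitnesses, n, lo, hi) {
  k <- length(positions)
  if (k < n) {
    pad <- stats::runif(n - k, lo, hi)
    return(list(positions = c(positions, pad),
                fitnesses = c(fitnesses, rep(NA_real_, n - k))))
  }
  best <- best_index(positions, fitnesses)
  rest <- setdiff(seq_len(k), best)
  take <- n - 1L
  if (take > 0L) {
    w <- vapply(rest, function(i) sum(abs(positions[i] - positions)),
                numeric(1))
    if (sum(w) <= 0) w <- rep(1, length(rest))
    chosen <- rest[sample.int(length(rest), take, prob = w)]
  } else chosen <- integer(0)
  idx <- c(best, chosen)
  list(positions = positions[idx], fitnesses = fitnesses[idx])
}

# Index of the best candidate; ties break to the smallest position so a
# flat landscape yields the smallest evaluated position.
best_index <- function(positions, fitnesses) {
  top <- max(fitnesses)
  cand <- which(fitnesses == top)
  cand[which.min(positions[cand])]
}

#' Fireworks-algorithm maximization
#'
#' Maximizes a bounded one-dimensional objective with the fireworks
#' algorithm: each generation, every firework emits explosion sparks
#' (count and amplitude allocated by fitness), Gaussian-mutation sparks
#' are added, out-of-bounds sparks are mapped back, and the next
#' generation is selected elitistically from the full candidate pool.
#' The best value ever seen (`best_val`) is tracked across generations
#' and never decreases. Ties in the objective break to the smallest
#' position.
#'
#' @param objective Vectorized function mapping positions in `[lo, hi)`
#'   to fitness values (see [threshold_objective] for the thresholding
#'   case). `-Inf` marks an infeasible position; `NaN` is an error.
#' @param config An [fa_config]; its `seed` makes the run deterministic.
#' @return An `fa_result`: `threshold` (best position rounded to an
#'   integer), `position` (best real position), `best_val` (its fitness),
#'   `history` (per-generation best fitness, non-decreasing), and
#'   `evaluations` (total objective calls).
#' @examples
#' res <- fa_optimize(function(x) -(x - 42)^2,
#'                    fa_config(seed = 1, lo = 0, hi = 255))
#' res$threshold
#' @export
fa_optimize <- function(objective, config = fa_config()) {
  validate_fa_config(config)
  if (!is.null(config$seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(config$seed)
  }
  lo <- config$lo; hi <- config$hi
  evals <- 0L
  eval_obj <- function(pos) {
    evals <<- evals + length(pos)
    f <- objective(pos)
    if (any(is.nan(f)))
      stop(sprintf("objective returned NaN at position %g",
                   pos[which(is.nan(f))[1L]]))
    f
  }

  pos <- stats::runif(config$n, lo, hi)
  fit <- eval_obj(pos)
  bi <- best_index(pos, fit)
  best_pos <- pos[bi]; best_val <- fit[bi]
  history <- numeric(config$iterations)

  for (g in seq_len(config$iterations)) {
    if (any(is.finite(fit))) {
      counts <- compute_spark_counts(fit, config)
      amps <- compute_amplitudes(fit, config)
    } else {
      # a wholly infeasible generation (-Inf everywhere): explore
      # uniformly at full amplitude until feasible ground is found
      counts <- rep(max(1L, as.integer(round(config$sparks / config$n))),
                    length(pos))
      amps <- rep(config$amplitude, length(pos))
    }
    spark_pos <- unlist(lapply(seq_along(pos), function(i)
      explode(pos[i], counts[i], max(amps[i], config$min_amplitude),
              lo, hi)))
    gauss_pos <- if (config$gaussian_sparks > 0L)
      vapply(seq_len(config$gaussian_sparks), function(j)
        gaussian_mutate(pos[sample.int(length(pos), 1L)], lo, hi),
        numeric(1))
    else numeric(0)
    new_pos <- c(spark_pos, gauss_pos)
    new_fit <- eval_obj(new_pos)

    cand_pos <- c(pos, new_pos)
    cand_fit <- c(fit, new_fit)
    bi <- best_index(cand_pos, cand_fit)
    if (cand_fit[bi] > best_val ||
        (cand_fit[bi] == best_val && cand_pos[bi] < best_pos)) {
      best_val <- cand_fit[bi]; best_pos <- cand_pos[bi]
    }
    history[g] <- best_val

    sel <- select_next_generation(cand_pos, cand_fit, config$n, lo, hi)
    pos <- sel$positions
    fit <- sel$fitnesses
    pad <- is.na(fit)
    if (any(pad)) fit[pad] <- eval_obj(pos[pad])
  }

  structure(list(threshold = as.integer(round(best_pos)),
                 position = best_pos, best_val = best_val,
                 history = history, evaluations = evals),
            class = "fa_result")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.fa_result <- function(x, ...) {
  cat(sprintf(paste0("<fa_result> threshold = %d, best_val = %.6g, ",
                     "%d objective evaluation(s)\n"),
              x$threshold, x$best_val, x$evaluations))
  invisible(x)
}

#' Fireworks-optimized threshold of a histogram
#'
#' Convenience wrapper: builds the [threshold_objective] for a histogram
#' and fitness criterion, runs [fa_optimize] over `[0, H - 2]`, and
#' returns the resulting integer threshold.
#'
#' @inheritParams exhaustive_best_threshold
#' @param config An [fa_config]; its bounds are overridden to the
#'   histogram's threshold domain.
#' @return The `fa_result`.
#' @export
fa_threshold <- function(hist, fitness = otsu_ratio_fitness,
                         config = fa_config()) {
  hist <- as_gray_histogram(hist)
  config$lo <- 0
  config$hi <- hist$levels - 2L
  # degenerate 2-level histograms have a single candidate threshold
  if (config$hi <= config$lo) {
    f <- fitness(hist, 0L)
    return(structure(list(threshold = 0L, position = 0, best_val = f,
                          history = f, evaluations = 1L),
                     class = "fa_result"))
  }
  fa_optimize(threshold_objective(hist, fitness), config)
}
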