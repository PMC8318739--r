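test_that("fa_config validates its parameters", {
  expect_error(fa_config(n = 1), "n")
  expect_error(fa_config(sparks = 3), "sparks")
  expect_error(fa_config(a = 0.9, b = 0.8), "a < b")
  expect_error(fa_config(iterations = 0), "iterations")
  expect_error(fa_config(lo = 5, hi = 5), "lo")
  expect_error(fa_config(min_amplitude = -1), "min_amplitude")
})

test_that("spark counts follow the fitness-proportional allocation", {
  cfg <- fa_config(n = 3, sparks = 6)
  expect_equal(compute_spark_counts(c(1, 2, 3), cfg), c(1L, 2L, 4L))

  cfg50 <- fa_config()
  expect_equal(compute_spark_counts(rep(2, 5), cfg50), rep(10L, 5))

  # single firework takes the whole (upper-bounded) budget
  expect_equal(compute_spark_counts(7, cfg50),
               as.integer(min(round(0.8 * 50), 50)))

  # monotone: better fireworks never get fewer sparks
  set.seed(11)
  for (k in 1:20) {
    f <- rnorm(5)
    s <- compute_spark_counts(f, cfg50)
    expect_true(all(diff(s[order(f)]) >= 0))
    expect_true(all(s >= 1))
  }
  expect_error(compute_spark_counts(numeric(0), cfg50), "fitness")
})

test_that("amplitudes shrink with fitness and stay within the cap", {
  cfg <- fa_config()
  a <- compute_amplitudes(c(1, 2, 3), cfg)
  expect_equal(a[1], 80 / 3, tolerance = 1e-6)
  expect_equal(a[2], 40 / 3, tolerance = 1e-6)
  expect_lt(a[3], 1e-6)
  expect_equal(compute_amplitudes(rep(5, 5), cfg), rep(8, 5))
  set.seed(12)
  for (k in 1:20) {
    f <- rnorm(5)
    amp <- compute_amplitudes(f, cfg)
    expect_true(all(amp >= 0 & amp <= cfg$amplitude))
    expect_true(all(diff(amp[order(f)]) <= 1e-12))
  }
})

test_that("modular boundary mapping lands in [lo, hi)", {
  expect_equal(map_to_bounds(100, 0, 255), 100)
  expect_equal(map_to_bounds(300, 0, 255), 45)
  expect_equal(map_to_bounds(-10, 0, 255), 10)
  set.seed(13)
  p <- runif(500, -1000, 1000)
  m <- map_to_bounds(p, 10, 200)
  expect_true(all(m >= 10 & m < 200))
})

test_that("explosion sparks stay within amplitude and are seeded", {
  set.seed(14)
  s0 <- explode(10, 50, 0, 0, 255)
  expect_true(all(s0 == 10))
  s <- explode(10, 200, 5, 0, 255)
  expect_true(all(s >= 5 & s <= 15))
  set.seed(99); a <- explode(100, 30, 20, 0, 255)
  set.seed(99); b <- explode(100, 30, 20, 0, 255)
  expect_identical(a, b)
})

test_that("gaussian mutation is multiplicative with Normal(1, 1) scale", {
  expect_equal(gaussian_mutate(0, 0, 255), 0) # origin is a fixed point
  set.seed(15)
  pre <- 100 * rnorm(10000, 1, 1) # the rule's pre-mapping distribution
  expect_lt(abs(mean(pre) - 100), 3 * 100 / sqrt(10000))
  set.seed(16); g1 <- gaussian_mutate(100, 0, 255)
  set.seed(16); g2 <- gaussian_mutate(100, 0, 255)
  expect_identical(g1, g2)
  expect_true(g1 >= 0 && g1 < 255)
})

test_that("next-generation selection is elitist and sized correctly", {
  pos <- c(1, 50, 100, 150, 200, 250)
  fit <- c(0.1, 0.9, 0.3, 0.2, 0.5, 0.4)
  set.seed(17)
  for (k in 1:10) {
    sel <- select_next_generation(pos, fit, 3, 0, 255)
    expect_length(sel$positions, 3)
    expect_true(50 %in% sel$positions) # unique maximum always survives
  }
  sel_all <- select_next_generation(pos, fit, 6, 0, 255)
  expect_setequal(sel_all$positions, pos)
  # identical positions: degenerate distances fall back to uniform choice
  sel_deg <- select_next_generation(rep(5, 4), rep(1, 4), 2, 0, 255)
  expect_equal(sel_deg$positions, c(5, 5))
  # too few candidates: kept and padded with in-bounds random positions
  sel_pad <- select_next_generation(c(5, 6), c(1, 2), 4, 0, 255)
  expect_length(sel_pad$positions, 4)
  expect_true(all(sel_pad$positions >= 0 & sel_pad$positions < 255))
  expect_equal(sum(is.na(sel_pad$fitnesses)), 2)
})

test_that("fa_optimize finds the analytic maximum of a smooth objective", {
  for (seed in 1:20) {
    res <- fa_optimize(function(x) -(x - 42)^2,
                       fa_config(seed = seed, lo = 0, hi = 255))
    expect_equal(res$threshold, 42L)
  }
})

test_that("fa_optimize matches the exhaustive oracle on the 4-level case", {
  h <- uniform4_histogram()
  for (seed in c(1, 7, 1234)) {
    res <- fa_threshold(h, config = fa_config(seed = seed))
    expect_equal(res$threshold, 1L)
    expect_equal(res$best_val, 4.0, tolerance = 1e-9)
  }
})

test_that("a flat landscape returns the smallest evaluated position", {
  res <- fa_optimize(function(x) rep(0, length(x)),
                     fa_config(seed = 5, lo = 0, hi = 255))
  expect_equal(res$best_val, 0)
  expect_lt(res$position, 5) # smallest of thousands of uniform draws
})

test_that("fa_optimize is deterministic, elitist and within budget", {
  h <- random_bimodal_histogram()
  cfg <- fa_config(seed = 21)
  r1 <- fa_threshold(h, config = cfg)
  r2 <- fa_threshold(h, config = cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history) >= 0))
  expect_equal(r1$best_val, max(r1$history))
  max_sparks <- cfg$n * round(cfg$b * cfg$sparks)
  budget <- cfg$n + cfg$iterations *
    (cfg$n + max_sparks + cfg$gaussian_sparks)
  expect_lte(r1$evaluations, budget)
})

test_that("mostly infeasible (-Inf) landscapes are still searched", {
  # feasible only on [200, 210); early generations may be all -Inf
  obj <- function(x) ifelse(x >= 200 & x < 210, -(x - 205)^2, -Inf)
  for (seed in 1:10) {
    res <- fa_optimize(obj, fa_config(seed = seed, lo = 0, hi = 254))
    expect_equal(res$threshold, 205L)
  }
})

test_that("NaN from the objective is reported with the position", {
  expect_error(
    fa_optimize(function(x) ifelse(x > 100, NaN, x),
                fa_config(seed = 2, lo = 0, hi = 255)),
    "NaN at position")
})

test_that("the RNG state outside fa_optimize is left untouched", {
  set.seed(1); before <- .Random.seed
  invisible(fa_optimize(function(x) -x^2, fa_config(seed = 9, lo = 0, hi = 10)))
  expect_identical(.Random.seed, before)
})
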